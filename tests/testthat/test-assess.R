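test_that("the margin is the weighted z-sum plus bias, with the sign rule", {
  m <- reference_model()
  z0 <- stats::setNames(rep(0, 4), m$metric_names)
  expect_equal(score(m, z0), 0)
  z1 <- stats::setNames(rep(1, 4), m$metric_names)
  expect_equal(score(m, z1), -2.8720)           # sum of published weights
  expect_equal(score(m, -z1), 2.8720)

  expect_identical(classify_score(2.8720), "skilled")
  expect_identical(classify_score(-2.8720), "novice")
  expect_identical(classify_score(0), "novice") # ambiguity fails to practice
  expect_error(classify_score(NaN), "finite")
  expect_error(score(m, z1[-1]), "missing")
})

test_that("class probabilities are a calibrated-shape logistic gradient", {
  p <- class_probabilities(0)
  expect_equal(p$p_skilled, 0.5)
  expect_equal(p$p_novice, 0.5)
  expect_equal(class_probabilities(-2.8720)$p_skilled, 1 / (1 + exp(2.8720)))
  expect_equal(class_probabilities(-2.8720)$p_skilled, 0.0536, tolerance = 5e-3)

  h <- seq(-25, 25, length.out = 10001)
  ps <- class_probabilities(h)$p_skilled
  expect_true(all(diff(ps) > 0))                       # strictly increasing
  expect_equal(ps + class_probabilities(h)$p_novice, rep(1, length(h)),
               tolerance = 1e-15)
  expect_equal(class_probabilities(-h)$p_skilled,
               class_probabilities(h)$p_novice, tolerance = 1e-15)
  expect_true(all(is.finite(class_probabilities(c(-800, 800))$p_skilled)))
})

test_that("per-metric verdicts follow the contribution sign at z = 0 boundary", {
  m <- reference_model()
  z <- stats::setNames(c(0, 0, -0.5, 0), m$metric_names)
  fb <- metric_feedback(m, z)
  row <- fb[fb$metric == "tip_distance_mean", ]
  expect_equal(row$contribution, 0.7451)
  expect_true(row$competent)
  expect_identical(row$message_key, "reinforce")

  z["tip_distance_mean"] <- 0.5
  row2 <- metric_feedback(m, z)[3, ]
  expect_equal(row2$contribution, -0.7451)
  expect_false(row2$competent)
  expect_identical(row2$message_key, "improve")

  # z = 0 sits on the proficiency benchmark: not yet competent
  expect_false(any(metric_feedback(m, z * 0)$competent))
})

test_that("metric importance ranks by weight magnitude with stable ties", {
  m <- reference_model()
  r <- rank_metrics(m)
  expect_identical(r[1], "tip_distance_mean")
  expect_identical(r[4], "acceleration_bipolar")

  tie <- fixed_model(c(a = 0.5, b = 0.5))
  expect_identical(rank_metrics(tie), c("a", "b"))
})

test_that("the margin decomposes exactly into contributions plus bias", {
  set.seed(10)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    m <- fixed_model(stats::setNames(rnorm(k), paste0("m", 1:k)),
                     bias = rnorm(1))
    z <- stats::setNames(rnorm(k), paste0("m", 1:k))
    fb <- metric_feedback(m, z)
    expect_equal(sum(fb$contribution) + m$bias, score(m, z),
                 tolerance = 1e-12)
    # all-competent + non-negative bias forces a skilled call
    if (all(fb$competent) && m$bias >= 0) {
      expect_identical(classify_score(score(m, z)), "skilled")
    }
  }
})

test_that("the two-step report gates on full step-1 competency", {
  m <- reference_model()
  zn <- stats::setNames(rep(-1, 4), m$metric_names)
  rep1 <- build_report(m, zn)   # identity normalization: raw values are z
  expect_identical(rep1$classification$label, "skilled")
  expect_true(all(rep1$steps[[1]]$metrics$competent))
  expect_true(rep1$step2_unlocked)
  expect_false(rep1$must_redo)

  zf <- stats::setNames(c(1, -1, -1, -1), m$metric_names)  # high bipolar force
  rep2 <- build_report(m, zf)
  expect_false(rep2$steps[[1]]$metrics$competent[1])
  expect_false(rep2$step2_unlocked)
  expect_true(rep2$must_redo)

  zm <- stats::setNames(c(-1, -1, 1, 1), m$metric_names)
  rep3 <- build_report(m, zm)
  expect_true(rep3$steps[[1]]$passed)
  expect_true(rep3$step2_unlocked)
  expect_false(rep3$must_redo)
  expect_identical(rep3$steps[[2]]$metrics$message_key, c("improve", "improve"))

  expect_error(build_report(m, zn, step_plan = list(s1 = m$metric_names[1:2])),
               "partition")
})

test_that("gate logic matches a brute-force truth table for up to 6 metrics", {
  set.seed(11)
  for (k in 2:6) {
    nms <- paste0("m", seq_len(k))
    n_safety <- sample(seq_len(k - 1), 1)
    cats <- sample(rep(c("safety", "movement"),
                       c(n_safety, k - n_safety)))
    w <- stats::setNames(sample(c(-1, 1), k, replace = TRUE) *
                           runif(k, 0.2, 2), nms)
    m <- fixed_model(w, bias = 0, categories = cats)
    for (pattern in 0:(2^k - 1)) {
      competent <- as.logical(bitwAnd(bitwShiftR(pattern, 0:(k - 1)), 1))
      # choose z so that sign(w_i z_i) realises the pattern
      z <- stats::setNames(ifelse(competent, sign(w), -sign(w)), nms)
      rep <- build_report(m, z)
      fb <- metric_feedback(m, z)
      expect_identical(fb$competent, competent)
      step1_all <- all(competent[cats == "safety"])
      expect_identical(rep$step2_unlocked, step1_all)
      expect_identical(rep$must_redo, !step1_all)
    }
  }
})

test_that("reports serialize and recordings assess end to end", {
  tab <- informative_table(n_per_group = 8, gap = 3, k_info = 2, k_noise = 0,
                           seed = 7)
  m <- voa_fit(tab, categories = c("safety", "movement"))
  v <- unlist(tab[1, c("informative_1", "informative_2")])
  rep <- build_report(m, v)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$classification$label, rep$classification$label)
  expect_equal(back$classification$p_skilled, rep$classification$p_skilled,
               tolerance = 1e-12)
  expect_identical(back$must_redo, rep$must_redo)

  co <- generate_cohort(cohort_spec(4, 4, seed = 3,
    skilled_profile = wide_gap_profiles(5)$skilled,
    novice_profile = wide_gap_profiles(5)$novice))
  fit <- voa_fit(extract_cohort_metrics(co))
  rpt <- assess_recording(fit, co$recordings[[1]])
  expect_s3_class(rpt, "voa_report")
  expect_identical(rpt$classification$label, "skilled")
  out <- capture.output(print(rpt))
  expect_true(any(grepl("Classification: SKILLED", out)))
})
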