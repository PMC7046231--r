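test_that("normalizer stores n-1 moments and rejects degenerate columns", {
  tab <- data.frame(a = c(2, 4, 6), b = c(1, 2, 4))
  p <- fit_normalizer(tab)
  expect_equal(unname(p$means["a"]), 4)
  expect_equal(unname(p$sds["a"]), 2)          # sample sd, n - 1

  z <- normalize_metrics(tab, p)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)

  expect_error(fit_normalizer(data.frame(a = c(5, 5, 5), b = 1:3)),
               "a")
  expect_error(fit_normalizer(data.frame(a = 1)), "2 rows")
})

test_that("normalization is the stated affine map and inverts exactly", {
  p <- structure(list(means = c(m = 10), sds = c(m = 2)),
                 class = "voa_normalizer")
  expect_equal(unname(normalize_metrics(c(m = 14), p)), 2)
  expect_equal(unname(normalize_metrics(c(m = 10), p)), 0)
  v <- c(m = 13.739)
  z <- normalize_metrics(v, p)
  expect_equal(unname(z * p$sds + p$means), unname(v), tolerance = 1e-12)
  expect_error(normalize_metrics(c(other = 1), p), "missing")
})

test_that("the trainer separates separable data with the expected geometry", {
  set.seed(1)
  lab <- rep(c("skilled", "novice"), each = 20)
  tab <- data.frame(m = c(rnorm(20, -1, 0.01), rnorm(20, 1, 0.01)))
  fit <- voa_fit(tab, lab)
  expect_lt(unname(coef(fit)["m"]), 0)         # skilled side is low values
  expect_identical(unname(predict(fit, tab)), lab)

  # label flip negates the solution exactly (origin start, symmetric loss)
  flip <- ifelse(lab == "skilled", "novice", "skilled")
  fit2 <- voa_fit(tab, flip)
  expect_equal(unname(coef(fit2)), -unname(coef(fit)), tolerance = 1e-12)

  # determinism
  fit3 <- voa_fit(tab, lab)
  expect_identical(coef(fit3), coef(fit))

  expect_error(voa_fit(tab, rep("skilled", 40)), "both classes")
  expect_error(voa_fit(tab, rep(c("expert", "novice"), each = 20)),
               "unknown group label")
})

test_that("the hinge cost is non-increasing across training iterations", {
  for (seed in c(2, 5)) {
    set.seed(seed)
    tab <- data.frame(m1 = rnorm(30), m2 = rnorm(30))
    lab <- rep(c("skilled", "novice"), 15)
    tab$m1 <- tab$m1 + ifelse(lab == "skilled", -0.8, 0.8)
    obj <- voa_fit(tab, lab)$training_meta$objective
    expect_true(all(diff(obj) <= 0))
  }
})

test_that("the trained direction agrees with an independent SVM solver", {
  set.seed(3)
  n <- 60
  lab <- rep(c("skilled", "novice"), each = n / 2)
  tab <- data.frame(m1 = rnorm(n), m2 = rnorm(n), m3 = rnorm(n))
  shift <- ifelse(lab == "skilled", -1.5, 1.5)
  tab$m1 <- tab$m1 + shift; tab$m2 <- tab$m2 + 0.5 * shift
  fit <- voa_fit(tab, lab)
  w_ours <- unname(coef(fit)[1:3])

  z <- scale(as.matrix(tab))
  ref <- e1071::svm(z, factor(lab, levels = c("novice", "skilled")),
                    kernel = "linear", scale = FALSE)
  w_ref <- drop(crossprod(ref$coefs, ref$SV))
  cosine <- sum(w_ours * w_ref) / sqrt(sum(w_ours^2) * sum(w_ref^2))
  expect_gt(cosine, 0.95)
})

test_that("generative hyperplanes are recovered on separable cohorts", {
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (seed in 1:10) {
    set.seed(seed)
    k <- 4
    w <- rnorm(k); w <- w / sqrt(sum(w^2))
    n <- 200
    y <- rep(c(1, -1), each = n / 2)
    x <- matrix(rnorm(n * k), n, k) + outer(1.5 * y, w)  # gap 3 sd along w
    tab <- as.data.frame(x); names(tab) <- paste0("m", 1:k)
    fit <- voa_fit(tab, ifelse(y > 0, "skilled", "novice"))
    expect_gte(cos_sim(unname(coef(fit)[1:k]), w), 0.95)
  }
})

test_that("confusion statistics agree with brute-force counting", {
  set.seed(8)
  tab <- informative_table(n_per_group = 8, gap = 1.2, k_info = 2, k_noise = 1,
                           seed = 8)
  res <- loocv(tab, iterations = 300)
  pred <- res$predictions
  expect_equal(sum(res$counts), nrow(tab))
  expect_equal(res$counts["skilled", "skilled"],
               sum(pred$truth == "skilled" & pred$predicted == "skilled"))
  expect_equal(res$counts["novice", "skilled"],
               sum(pred$truth == "novice" & pred$predicted == "skilled"))
  expect_equal(res$accuracy, 100 * mean(pred$truth == pred$predicted))
  expect_equal(res$sensitivity,
               100 * mean(pred$predicted[pred$truth == "skilled"] == "skilled"))
  expect_equal(res$specificity,
               100 * mean(pred$predicted[pred$truth == "novice"] == "novice"))
})

test_that("each LOOCV fold refits without the held-out member", {
  tab <- informative_table(n_per_group = 6, gap = 2, k_info = 2, k_noise = 0,
                           seed = 3)
  res <- loocv(tab, iterations = 300)
  x <- tab[, c("informative_1", "informative_2")]
  for (i in c(1, 5, 12)) {
    fit_i <- voa_fit(x[-i, ], tab$group[-i], iterations = 500)
    expect_identical(unname(predict(fit_i, x[i, , drop = FALSE])),
                     res$predictions$predicted[i])
    # the held-out member's value must not sit in the fold's normalization
    norm_i <- fit_normalizer(x[-i, ])
    expect_equal(fit_i$normalization$means, norm_i$means)
  }
  expect_error(loocv(tab[1:2, ]), "at least 3")
})

test_that("selection handles a single candidate and keeps its invariant", {
  tab <- informative_table(n_per_group = 8, gap = 2, k_info = 1, k_noise = 0,
                           seed = 2)
  sel <- select_metrics(tab, iterations = 200)
  expect_identical(sel$selected, "informative_1")
  expect_equal(nrow(sel$trace), 1)
  expect_identical(sel$trace$phase, "forward")

  tab2 <- informative_table(n_per_group = 10, gap = 2, k_info = 2, k_noise = 2,
                            seed = 4)
  sel2 <- select_metrics(tab2, iterations = 200)
  expect_equal(sel2$accuracy, max(sel2$trace$accuracy))
  expect_error(select_metrics(tab2[, "group", drop = FALSE]), "empty candidate")
})
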