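# Fixtures built in code: analytic recordings with known metric values and
# compact synthetic cohorts.

# Static tips at fixed offset; constant forces; linear bleeding.
static_recording <- function(n = 100, dt = 0.05,
                             ua = c(0, 0, 0), bp = c(3, 4, 0),
                             ua_force = 0.2, bp_force = 0.2,
                             bleed_rate = 0.05) {
  t <- (seq_len(n) - 1) * dt
  raw_recording(
    t = t,
    ua_pos = matrix(ua, n, 3, byrow = TRUE),
    bp_pos = matrix(bp, n, 3, byrow = TRUE),
    ua_force = rep(ua_force, n), bp_force = rep(bp_force, n),
    blood_ml = bleed_rate * t
  )
}

# Quadratic bipolar path x(t) = a t^2 / 2: constant acceleration `a`.
quadratic_recording <- function(a = 10, n = 101, dt = 0.05) {
  t <- (seq_len(n) - 1) * dt
  raw_recording(
    t = t,
    ua_pos = matrix(0, n, 3),
    bp_pos = cbind(0.5 * a * t^2, 0, 0),
    ua_force = rep(0.1, n), bp_force = rep(0.1, n),
    blood_ml = rep(0, n)
  )
}

# Tightly separated two-group profiles; gap on every validated metric is
# many pooled standard deviations.
wide_gap_profiles <- function(duration_s = 20) {
  list(
    skilled = sim_profile("skilled", duration_s = duration_s,
                          force_mean_n = c(ua = 0.6, bp = 0.5),
                          force_jitter_n = c(ua = 0.05, bp = 0.05),
                          tip_separation_mean_mm = 5, tip_separation_sd_mm = 0.5,
                          tremor_accel_mm_s2 = 20,
                          bleed_rate_ml_s = 0.02, bleed_jitter_frac = 0.05),
    novice = sim_profile("novice", duration_s = duration_s,
                         force_mean_n = c(ua = 2.5, bp = 2.5),
                         force_jitter_n = c(ua = 0.05, bp = 0.05),
                         tip_separation_mean_mm = 60, tip_separation_sd_mm = 0.5,
                         tremor_accel_mm_s2 = 120,
                         bleed_rate_ml_s = 0.20, bleed_jitter_frac = 0.05)
  )
}

# Metric table with known informative/noise structure (novices shifted by
# `gap` group means on the informative columns; unit within-group sd).
informative_table <- function(n_per_group = 30, gap = 3, k_info = 2,
                              k_noise = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("skilled", "novice"), each = n_per_group)
  shift <- ifelse(group == "novice", gap, 0)
  named_cols <- function(k, prefix, gen) {
    out <- lapply(seq_len(k), gen)
    names(out) <- sprintf("%s_%d", prefix, seq_len(k))
    out
  }
  cols <- c(named_cols(k_info, "informative", function(i) rnorm(n, shift)),
            named_cols(k_noise, "noise", function(i) rnorm(n)))
  cbind(data.frame(group = group), as.data.frame(cols))
}

# A small fitted model with prescribed weights/bias and identity
# normalization, for assessment-side tests.
fixed_model <- function(weights, bias = 0, categories = NULL) {
  k <- length(weights)
  nms <- names(weights) %||% paste0("m", seq_len(k))
  categories <- categories %||% rep(c("safety", "movement"), length.out = k)
  norm <- structure(list(means = stats::setNames(rep(0, k), nms),
                         sds = stats::setNames(rep(1, k), nms)),
                    class = "voa_normalizer")
  voa:::new_voa_model(nms, unname(weights), bias, norm, categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
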