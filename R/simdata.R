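#' Simulation profile for one skill group
#'
#' Describes the generative parameters of synthetic simulator trials for one
#' skill group. Skilled operators are expected to show lower applied force,
#' lower bleeding rate, smaller inter-tip distance (closer bimanual
#' coordination) and lower tremor acceleration than novices; the group
#' separation the generator produces is controlled entirely through these
#' parameters.
#'
#' @param group_label `"skilled"` or `"novice"`.
#' @param duration_s Trial duration in seconds (> 0).
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param force_mean_n,force_jitter_n Mean and jitter (sd) of the applied
#'   force in newtons; either a single value for both instruments or a named
#'   vector `c(ua = ..., bp = ...)`.
#' @param tip_separation_mean_mm,tip_separation_sd_mm Across-trial mean and sd
#'   of the bipolar-to-aspirator tip distance, millimetres.
#' @param tremor_accel_mm_s2 Scale of the tremor acceleration in mm/s^2; the
#'   mean second-difference acceleration of the generated tip paths is
#'   approximately this value. Zero gives exactly quiescent tips (constant
#'   velocity, zero acceleration).
#' @param bleed_rate_ml_s Mean bleeding rate, mL/s.
#' @param bleed_jitter_frac Relative sd of the piecewise-constant segment
#'   bleeding rates (0 = exactly linear accumulation).
#' @param seed Default seed used when the profile is simulated directly.
#' @return A `voa_profile` list.
#' @export
sim_profile <- function(group_label = c("skilled", "novice"),
                        duration_s = 120, sample_rate_hz = 20,
                        force_mean_n = c(ua = 0.8, bp = 0.5),
                        force_jitter_n = c(ua = 0.15, bp = 0.12),
                        tip_separation_mean_mm = 8,
                        tip_separation_sd_mm = 2,
                        tremor_accel_mm_s2 = 30,
                        bleed_rate_ml_s = 0.04,
                        bleed_jitter_frac = 0.1,
                        seed = 1L) {
  group_label <- match.arg(group_label)
  force_mean_n <- expand_instrument(force_mean_n, "force_mean_n")
  force_jitter_n <- expand_instrument(force_jitter_n, "force_jitter_n")
  if (duration_s <= 0 || sample_rate_hz <= 0) {
    stop_input("`duration_s` and `sample_rate_hz` must be positive")
  }
  scales <- c(force_mean_n, force_jitter_n, tip_separation_mean_mm,
              tip_separation_sd_mm, tremor_accel_mm_s2, bleed_rate_ml_s,
              bleed_jitter_frac)
  if (any(scales < 0)) stop_input("scale parameters must be non-negative")
  if (round(duration_s * sample_rate_hz) < 2) {
    stop_input("duration_s * sample_rate_hz must give at least 2 samples")
  }
  structure(
    list(group_label = group_label, duration_s = duration_s,
         sample_rate_hz = sample_rate_hz,
         force_mean_n = force_mean_n, force_jitter_n = force_jitter_n,
         tip_separation_mean_mm = tip_separation_mean_mm,
         tip_separation_sd_mm = tip_separation_sd_mm,
         tremor_accel_mm_s2 = tremor_accel_mm_s2,
         bleed_rate_ml_s = bleed_rate_ml_s,
         bleed_jitter_frac = bleed_jitter_frac,
         seed = as.integer(seed)),
    class = "voa_profile"
  )
}

expand_instrument <- function(x, what) {
  if (length(x) == 1L) x <- c(ua = unname(x), bp = unname(x))
  if (length(x) != 2L || !all(c("ua", "bp") %in% names(x))) {
    stop_input("`", what, "` must be a single value or c(ua = ..., bp = ...)")
  }
  x[c("ua", "bp")]
}

#' Default group profiles
#'
#' The package's reference conditions for the two skill groups: novices apply
#' roughly twice the bipolar force of skilled operators, bleed 2.5x faster,
#' hold the instrument tips about twice as far apart and show more than twice
#' the tremor acceleration.
#'
#' @param group `"skilled"` or `"novice"`.
#' @return A `voa_profile`.
#' @export
default_profile <- function(group = c("skilled", "novice")) {
  group <- match.arg(group)
  if (group == "skilled") {
    sim_profile("skilled")
  } else {
    sim_profile("novice",
                force_mean_n = c(ua = 1.2, bp = 1.0),
                force_jitter_n = c(ua = 0.30, bp = 0.28),
                tip_separation_mean_mm = 15, tip_separation_sd_mm = 4,
                tremor_accel_mm_s2 = 80, bleed_rate_ml_s = 0.10)
  }
}

#' Cohort specification
#'
#' @param n_skilled,n_novice Member counts (default 28 skilled, 22 novice,
#'   matching the reference cohort composition).
#' @param skilled_profile,novice_profile `voa_profile` templates.
#' @param seed Master seed; per-member seeds are derived with [mix_seed()].
#' @return A `voa_cohort_spec`.
#' @export
cohort_spec <- function(n_skilled = 28, n_novice = 22,
                        skilled_profile = default_profile("skilled"),
                        novice_profile = default_profile("novice"),
                        seed = 1L) {
  stopifnot(inherits(skilled_profile, "voa_profile"),
            inherits(novice_profile, "voa_profile"))
  n_skilled <- as.integer(n_skilled); n_novice <- as.integer(n_novice)
  if (n_skilled < 0 || n_novice < 0 || n_skilled + n_novice < 2) {
    stop_input("cohort needs at least 2 members")
  }
  structure(
    list(n_skilled = n_skilled, n_novice = n_novice,
         skilled_profile = skilled_profile, novice_profile = novice_profile,
         seed = as.integer(seed)),
    class = "voa_cohort_spec"
  )
}

# Damping constants of the leaky double integration that turns white
# tremor acceleration into bounded tip displacement.
TREMOR_VEL_DECAY <- 0.90
TREMOR_POS_DECAY <- 0.99
# E|N3(0, I)| = sqrt(2) * gamma(2) / gamma(3/2): converts the per-axis
# acceleration sd into the mean 3-D acceleration magnitude.
CHI3_MEAN <- sqrt(2) * gamma(2) / gamma(1.5)

#' Generate one synthetic simulator recording
#'
#' Tip paths are a constant-velocity drift plus damped, twice-(leakily)-
#' integrated Gaussian tremor acceleration; the bipolar tip is offset from the
#' aspirator tip by a per-trial separation vector. Forces are Gaussian jitter
#' around the instrument mean, clamped at zero. Blood volume accumulates with
#' a piecewise-constant jittered rate, so it is non-decreasing by
#' construction. Deterministic for fixed `(profile, seed)`.
#'
#' @param profile A `voa_profile`.
#' @param seed Seed; defaults to the profile's own.
#' @return A [raw_recording()] object.
#' @export
generate_recording <- function(profile, seed = profile$seed) {
  stopifnot(inherits(profile, "voa_profile"))
  n <- round(profile$duration_s * profile$sample_rate_hz)
  if (n < 2) stop_input("profile yields fewer than 2 samples")
  dt <- 1 / profile$sample_rate_hz
  with_seed(seed, {
    t <- (seq_len(n) - 1) * dt

    # aspirator base path: random start, slow constant-velocity drift
    ua_base <- matrix(rnorm(3, 0, 2), n, 3, byrow = TRUE) +
      outer(t, rnorm(3, 0, 0.4))

    # per-trial separation vector from aspirator to bipolar tip
    sep_dir <- rnorm(3)
    sep_dir <- sep_dir / sqrt(sum(sep_dir^2))
    sep_len <- max(0.1, rnorm(1, profile$tip_separation_mean_mm,
                              profile$tip_separation_sd_mm))
    bp_base <- ua_base + matrix(sep_dir * sep_len, n, 3, byrow = TRUE)

    sd_a <- profile$tremor_accel_mm_s2 / CHI3_MEAN
    ua_pos <- ua_base + tremor_displacement(n, dt, sd_a)
    bp_pos <- bp_base + tremor_displacement(n, dt, sd_a)

    ua_force <- pmax(0, rnorm(n, profile$force_mean_n[["ua"]],
                              profile$force_jitter_n[["ua"]]))
    bp_force <- pmax(0, rnorm(n, profile$force_mean_n[["bp"]],
                              profile$force_jitter_n[["bp"]]))

    # ~10 constant-rate segments; non-negative rates keep volume monotone
    n_seg <- max(1L, min(10L, n - 1L))
    seg_rate <- pmax(0, rnorm(n_seg, profile$bleed_rate_ml_s,
                              profile$bleed_rate_ml_s * profile$bleed_jitter_frac))
    seg_of <- pmin(n_seg, ceiling(seq_len(n - 1) / ((n - 1) / n_seg)))
    blood_ml <- c(0, cumsum(seg_rate[seg_of] * dt))

    raw_recording(t, ua_pos, bp_pos, ua_force, bp_force, blood_ml)
  })
}

# White acceleration -> leaky velocity -> leaky displacement (per axis).
tremor_displacement <- function(n, dt, sd_a) {
  if (sd_a == 0) return(matrix(0, n, 3))
  a <- matrix(rnorm(n * 3, 0, sd_a), n, 3)
  d <- matrix(0, n, 3)
  v <- numeric(3)
  p <- numeric(3)
  for (k in seq_len(n)) {
    v <- TREMOR_VEL_DECAY * v + a[k, ] * dt
    p <- TREMOR_POS_DECAY * p + v * dt
    d[k, ] <- p
  }
  d
}

#' Generate a labelled synthetic cohort
#'
#' Member `i` of the cohort (skilled members first) is generated with seed
#' `mix_seed(spec$seed, i)`, so the cohort is reproducible member-by-member.
#'
#' @param spec A [cohort_spec()].
#' @param require_both_classes Error if either class is empty (any training
#'   use needs both).
#' @return A list with elements `recordings` (list of `voa_recording`),
#'   `group` (character vector) and `trial_id`.
#' @export
generate_cohort <- function(spec, require_both_classes = TRUE) {
  stopifnot(inherits(spec, "voa_cohort_spec"))
  if (require_both_classes && (spec$n_skilled < 1 || spec$n_novice < 1)) {
    stop_input("cohort must contain at least one member of each class")
  }
  group <- c(rep("skilled", spec$n_skilled), rep("novice", spec$n_novice))
  recs <- vector("list", length(group))
  for (i in seq_along(group)) {
    prof <- if (group[i] == "skilled") spec$skilled_profile else spec$novice_profile
    recs[[i]] <- generate_recording(prof, seed = mix_seed(spec$seed, i))
  }
  list(recordings = recs, group = group,
       trial_id = sprintf("trial_%03d", seq_along(group)))
}

#' Write a cohort to disk (recording CSVs + manifest)
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV (`trial_id,file,group`), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.csv", cohort$trial_id)
  for (i in seq_along(cohort$recordings)) {
    write_recording(cohort$recordings[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(trial_id = cohort$trial_id, file = files,
                         group = cohort$group)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
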