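#' Construct a raw simulator recording
#'
#' A recording holds the time-aligned channels the simulator exports for one
#' trial: 3-D tip positions and applied force for the ultrasonic aspirator
#' (`ua`, dominant hand) and the bipolar forceps (`bp`, non-dominant hand),
#' plus cumulative blood loss. Units are seconds, millimetres, newtons and
#' millilitres.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param ua_pos,bp_pos Numeric matrices, one row per sample, three columns
#'   (x, y, z) in millimetres.
#' @param ua_force,bp_force Non-negative force traces in newtons.
#' @param blood_ml Cumulative blood volume in millilitres, non-decreasing.
#' @return An object of class `voa_recording`.
#' @export
raw_recording <- function(t, ua_pos, bp_pos, ua_force, bp_force, blood_ml) {
  ua_pos <- as.matrix(ua_pos)
  bp_pos <- as.matrix(bp_pos)
  n <- length(t)
  if (n < 2L) stop_input("a recording needs at least 2 samples")
  if (any(diff(t) <= 0)) stop_input("`t` must be strictly increasing")
  if (nrow(ua_pos) != n || nrow(bp_pos) != n ||
      ncol(ua_pos) != 3L || ncol(bp_pos) != 3L) {
    stop_input("tip position matrices must be n x 3 and match length(t)")
  }
  if (length(ua_force) != n || length(bp_force) != n ||
      length(blood_ml) != n) {
    stop_input("all channels must have the same length as `t`")
  }
  if (any(!is.finite(t)) || any(!is.finite(ua_pos)) || any(!is.finite(bp_pos)) ||
      any(!is.finite(ua_force)) || any(!is.finite(bp_force)) ||
      any(!is.finite(blood_ml))) {
    stop_input("recording channels must be finite")
  }
  if (any(ua_force < 0) || any(bp_force < 0)) {
    stop_input("forces must be non-negative")
  }
  if (any(diff(blood_ml) < -1e-12)) {
    stop_input("`blood_ml` must be non-decreasing")
  }
  colnames(ua_pos) <- colnames(bp_pos) <- c("x", "y", "z")
  structure(
    list(t = as.numeric(t), ua_pos = ua_pos, bp_pos = bp_pos,
         ua_force = as.numeric(ua_force), bp_force = as.numeric(bp_force),
         blood_ml = as.numeric(blood_ml)),
    class = "voa_recording"
  )
}

#' @export
print.voa_recording <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1]
  cat(sprintf("<voa_recording: %d samples over %.1f s>\n", length(x$t), dur))
  cat(sprintf("  max bipolar force %.3f N, blood loss %.2f mL\n",
              max(x$bp_force), x$blood_ml[length(x$blood_ml)] - x$blood_ml[1]))
  invisible(x)
}

recording_columns <- c("t", "ua_x", "ua_y", "ua_z", "ua_force",
                       "bp_x", "bp_y", "bp_z", "bp_force", "blood_ml")

#' Write / read a recording as CSV
#'
#' One file per trial with header
#' `t,ua_x,ua_y,ua_z,ua_force,bp_x,bp_y,bp_z,bp_force,blood_ml`.
#'
#' @param rec A `voa_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `voa_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "voa_recording"))
  df <- data.frame(
    t = rec$t,
    ua_x = rec$ua_pos[, 1], ua_y = rec$ua_pos[, 2], ua_z = rec$ua_pos[, 3],
    ua_force = rec$ua_force,
    bp_x = rec$bp_pos[, 1], bp_y = rec$bp_pos[, 2], bp_z = rec$bp_pos[, 3],
    bp_force = rec$bp_force,
    blood_ml = rec$blood_ml
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(recording_columns, names(df))
  if (length(missing)) {
    stop_input("recording CSV missing columns: ", paste(missing, collapse = ", "))
  }
  raw_recording(
    t = df$t,
    ua_pos = cbind(df$ua_x, df$ua_y, df$ua_z),
    bp_pos = cbind(df$bp_x, df$bp_y, df$bp_z),
    ua_force = df$ua_force, bp_force = df$bp_force,
    blood_ml = df$blood_ml
  )
}
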