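#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a per-member seed from a cohort seed
#'
#' Portable mixing rule used to give every cohort member its own
#' reproducible stream: `(seed * 48271 + index * 8191 + 1) mod (2^31 - 1)`.
#' All arithmetic is exact in double precision (products stay below 2^53),
#' so the rule reproduces identically across platforms and languages.
#'
#' @param seed Integer master seed.
#' @param index 1-based member index.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
mix_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), length(seed) == 1L,
            length(index) == 1L)
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 8191 + 1
  as.integer(s %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
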