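# Small shared helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; prevalence tables in this package
#' follow the half-up convention common in clinical reporting (11.25 -> 11.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Draw from a normal truncated to [lo, hi] by rejection; vectorised n.
# Fine for the mild truncations used here (at worst ~1.5 SD into the tail).
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
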