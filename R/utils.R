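#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when reporting monetary amounts,
#' as opposed to the round-half-even rule of [base::round()]. A small
#' epsilon guards against binary floating-point representations of
#' decimal values (e.g. 254.15) falling just below the .5 boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# truncated-normal draw by rejection; bounds assumed to contain
# non-negligible mass for the parameter ranges used here
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                             if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_negative <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# deterministic child seed for scenario/bootstrap streams, kept < 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) + 7919 * as.double(index)) %% 2147483629L)
}
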