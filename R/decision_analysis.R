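#' Incremental cost-effectiveness ratio
#'
#' Ratio of incremental cost to incremental effect. When the new
#' strategy is both cheaper and more effective (negative incremental
#' cost, positive incremental effect) it dominates the comparator: the
#' ratio is still computed but flagged, and reports suppress it.
#'
#' @param delta_cost incremental cost (EUR).
#' @param delta_effect incremental effect (nonzero).
#' @return list with `value` (the ratio), `dominant` (logical), and
#'   `dominated` (logical: more costly and less effective).
#' @examples
#' icer(189, 0.30)    # 630
#' icer(-1121, 0.30)  # dominant
#' @export
icer <- function(delta_cost, delta_effect) {
  if (!is.finite(delta_cost) || !is.finite(delta_effect)) {
    stop("incremental cost and effect must be finite", call. = FALSE)
  }
  if (delta_effect == 0) {
    stop("ICER undefined: incremental effect is zero", call. = FALSE)
  }
  list(value = delta_cost / delta_effect,
       dominant = delta_cost < 0 && delta_effect > 0,
       dominated = delta_cost > 0 && delta_effect < 0)
}

#' Classify cost-effectiveness plane quadrants
#'
#' Effects on the horizontal axis, costs on the vertical axis. Boundary
#' convention: zero incremental cost counts as "not more costly"
#' (south), zero incremental effect as "not more effective" (west) —
#' cosmetic for continuous clouds, but fixed and documented.
#'
#' @param delta_cost,delta_effect numeric vectors (recycled).
#' @return character vector in `c("NE", "NW", "SE", "SW")`.
#' @export
classify_quadrant <- function(delta_cost, delta_effect) {
  if (any(!is.finite(delta_cost)) || any(!is.finite(delta_effect))) {
    stop("incremental pairs must be finite", call. = FALSE)
  }
  east <- delta_effect > 0
  north <- delta_cost > 0
  ifelse(east & north, "NE",
         ifelse(east & !north, "SE",
                ifelse(!east & north, "NW", "SW")))
}

#' Quadrant distribution of a bootstrap cloud
#'
#' @param cloud a `sur_cloud` or a data.frame with `delta_cost` and
#'   `delta_effect` columns.
#' @return named numeric vector of percentages over `NE`, `NW`, `SE`,
#'   `SW` (summing to 100 before rounding); attribute `"rounded"` holds
#'   the whole-percent version used in reports.
#' @export
quadrant_distribution <- function(cloud) {
  pairs <- if (inherits(cloud, "sur_cloud")) cloud$pairs else as.data.frame(cloud)
  if (nrow(pairs) == 0) stop("empty bootstrap cloud", call. = FALSE)
  q <- classify_quadrant(pairs$delta_cost, pairs$delta_effect)
  pct <- 100 * vapply(c(NE = "NE", NW = "NW", SE = "SE", SW = "SW"),
                      function(k) mean(q == k), numeric(1))
  attr(pct, "rounded") <- round(pct)
  pct
}

#' Willingness-to-pay grid
#'
#' Default grids for the acceptability curve: 0 to 50,000 EUR in steps
#' of 250 per QALY, 0 to 5,000 EUR in steps of 50 per symptom-free
#' individual.
#'
#' @param outcome `"qaly"` or `"symptom_free"`.
#' @param lambdas optional explicit grid (nondecreasing, starting at 0).
#' @return numeric vector of willingness-to-pay thresholds.
#' @export
wtp_grid <- function(outcome = c("qaly", "symptom_free"), lambdas = NULL) {
  if (!is.null(lambdas)) {
    if (lambdas[1] != 0 || is.unsorted(lambdas) || any(lambdas < 0)) {
      stop("'lambdas' must be nondecreasing, non-negative, starting at 0",
           call. = FALSE)
    }
    return(lambdas)
  }
  outcome <- match.arg(outcome)
  if (outcome == "qaly") seq(0, 50000, by = 250) else seq(0, 5000, by = 50)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective: the fraction of bootstrap replicates
#' with positive net monetary benefit, lambda * delta_effect -
#' delta_cost > 0 (ties count as not cost-effective).
#'
#' @param cloud a `sur_cloud` or data.frame of incremental pairs.
#' @param lambdas willingness-to-pay grid (see [wtp_grid()]).
#' @return data.frame with columns `lambda` and `probability`.
#' @export
ceac <- function(cloud, lambdas = wtp_grid("qaly")) {
  pairs <- if (inherits(cloud, "sur_cloud")) cloud$pairs else as.data.frame(cloud)
  if (nrow(pairs) == 0) stop("empty bootstrap cloud", call. = FALSE)
  prob <- vapply(lambdas, function(l) {
    mean(l * pairs$delta_effect - pairs$delta_cost > 0)
  }, numeric(1))
  data.frame(lambda = lambdas, probability = prob)
}

#' Bootstrap-acceptability confidence interval for the ICER
#'
#' Orders the replicates by their angle on the cost-effectiveness plane
#' — a ray rotating counterclockwise from the south axis, so the
#' south-east (dominance) quadrant comes first and the north-west
#' (dominated) quadrant last, respecting dominance ordering — and
#' returns the ICERs of the replicates at the (1 +/- level)/2 positions
#' of that ordering. The interval may legitimately contain negative
#' values when the cloud straddles quadrants.
#'
#' @param cloud a `sur_cloud` or data.frame of incremental pairs
#'   (>= 100 rows).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` of ICER values.
#' @export
icer_acceptability_ci <- function(cloud, level = 0.95) {
  pairs <- if (inherits(cloud, "sur_cloud")) cloud$pairs else as.data.frame(cloud)
  if (nrow(pairs) < 100) stop("need at least 100 replicates", call. = FALSE)
  # angle from the south axis (0, -1), counterclockwise: SE in (0, pi/2),
  # NE in (pi/2, pi), NW in (pi, 3pi/2), SW in (3pi/2, 2pi)
  theta <- (atan2(pairs$delta_cost, pairs$delta_effect) + pi / 2) %% (2 * pi)
  ord <- order(theta)
  n <- length(ord)
  alpha <- (1 - level) / 2
  lo_pos <- max(1L, floor(alpha * (n + 1)))
  hi_pos <- min(n, ceiling((1 - alpha) * (n + 1)))
  ratio <- pairs$delta_cost / pairs$delta_effect
  c(ratio[ord[lo_pos]], ratio[ord[hi_pos]])
}

#' Summarize a bootstrap cloud into a decision-analytic result
#'
#' Combines the point estimates, BCa intervals for incremental cost and
#' effect, the ICER with its bootstrap-acceptability interval, the
#' cost-effectiveness plane quadrant distribution, and the acceptability
#' curve into one result object.
#'
#' @param cloud a `sur_cloud` from [bootstrap_sur()].
#' @param jackknife optional matrix from [jackknife_sur()] for the BCa
#'   acceleration.
#' @param level confidence level (default 0.95).
#' @param lambdas willingness-to-pay grid for the acceptability curve.
#' @param icer_convention `"ratio_of_means"` (ICER of the point
#'   estimates; default) or `"mean_of_ratios"` (bootstrap mean of
#'   per-replicate ICERs).
#' @return object of class `ee_result`.
#' @export
evaluate_cloud <- function(cloud, jackknife = NULL, level = 0.95,
                           lambdas = wtp_grid("qaly"),
                           icer_convention = c("ratio_of_means",
                                               "mean_of_ratios")) {
  stopifnot(inherits(cloud, "sur_cloud"))
  icer_convention <- match.arg(icer_convention)
  pt <- cloud$point_estimate
  dc_ci <- bca_ci(cloud$pairs$delta_cost, pt$delta_cost,
                  if (!is.null(jackknife)) jackknife[, "delta_cost"],
                  level = level)
  de_ci <- bca_ci(cloud$pairs$delta_effect, pt$delta_effect,
                  if (!is.null(jackknife)) jackknife[, "delta_effect"],
                  level = level)
  ic <- icer(pt$delta_cost, pt$delta_effect)
  icer_value <- if (icer_convention == "ratio_of_means") ic$value else
    mean(cloud$pairs$delta_cost / cloud$pairs$delta_effect)
  structure(list(
    delta_cost = pt$delta_cost, delta_cost_ci = as.numeric(dc_ci),
    delta_effect = pt$delta_effect, delta_effect_ci = as.numeric(de_ci),
    icer = icer_value, icer_ci = icer_acceptability_ci(cloud, level),
    dominant = ic$dominant, dominated = ic$dominated,
    icer_convention = icer_convention,
    quadrants = quadrant_distribution(cloud),
    ceac = ceac(cloud, lambdas),
    level = level, B = cloud$B, seed = cloud$seed,
    n_redrawn = cloud$n_redrawn
  ), class = "ee_result")
}

#' @export
print.ee_result <- function(x, ...) {
  cat(sprintf("Economic evaluation (B = %d bootstrap replicates)\n", x$B))
  cat(sprintf("  incremental cost:   %8.0f  (%.0f%% CI %0.0f to %0.0f)\n",
              x$delta_cost, 100 * x$level,
              x$delta_cost_ci[1], x$delta_cost_ci[2]))
  cat(sprintf("  incremental effect: %8.4f  (%.0f%% CI %0.4f to %0.4f)\n",
              x$delta_effect, 100 * x$level,
              x$delta_effect_ci[1], x$delta_effect_ci[2]))
  if (isTRUE(x$dominant)) {
    cat("  ICER: dominant (more effective, less costly)\n")
  } else {
    cat(sprintf("  ICER: %0.0f  (%.0f%% CI %0.0f to %0.0f)\n",
                x$icer, 100 * x$level, x$icer_ci[1], x$icer_ci[2]))
  }
  q <- attr(x$quadrants, "rounded")
  cat(sprintf("  CE plane %%: NE %g | NW %g | SE %g | SW %g\n",
              q["NE"], q["NW"], q["SE"], q["SW"]))
  invisible(x)
}
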