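#' Select dropout predictors by logistic regression
#'
#' Regresses the missingness indicator on each candidate baseline
#' covariate and keeps those associated with dropout below the screening
#' p-value. Used to augment the imputation model so that bias from
#' differential loss to follow-up is corrected.
#'
#' @param data analysis data.frame.
#' @param miss_col name of a logical column flagging missing follow-up.
#' @param candidates character vector of candidate baseline columns.
#' @param alpha screening threshold (default 0.2).
#' @return character vector (possibly empty) of selected predictors.
#' @export
select_dropout_predictors <- function(data, miss_col, candidates,
                                      alpha = 0.2) {
  stopifnot(miss_col %in% names(data))
  y <- as.integer(data[[miss_col]])
  if (length(unique(y)) < 2) return(character(0))
  keep <- vapply(candidates, function(v) {
    x <- data[[v]]
    if (is.null(x) || stats::sd(x, na.rm = TRUE) == 0) return(FALSE)
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    p <- summary(fit)$coefficients
    nrow(p) >= 2 && p[2, 4] < alpha
  }, logical(1))
  candidates[keep]
}

#' Deterministic regression imputation of missing follow-up values
#'
#' For each target variable with missing entries, fits a least-squares
#' regression on the predictor set using the complete records and
#' replaces missing values by the fitted means (no residual draw, so the
#' procedure is deterministic). Predictors should be the union of
#' outcome predictors and dropout predictors so the imputation corrects
#' for covariate-dependent (missing-at-random) dropout.
#'
#' @param data analysis data.frame; predictor columns must be complete.
#' @param vars character vector of columns to impute.
#' @param predictors character vector of predictor columns.
#' @return `data` with missing `vars` filled in; attribute `"imputed"`
#'   holds, per variable, the row indices that were imputed.
#' @export
regression_impute <- function(data, vars, predictors) {
  stopifnot(all(vars %in% names(data)), all(predictors %in% names(data)))
  for (p in predictors) {
    if (all(is.na(data[[p]]))) {
      stop(sprintf("predictor column '%s' is entirely missing", p),
           call. = FALSE)
    }
  }
  imputed <- list()
  for (v in vars) {
    y <- as.numeric(data[[v]])
    miss <- which(is.na(y))
    imputed[[v]] <- miss
    if (length(miss) == 0) next
    if (length(miss) == nrow(data)) {
      stop(sprintf("cannot impute '%s': no observed values", v), call. = FALSE)
    }
    f <- stats::reformulate(predictors, response = "..y..")
    d <- data[predictors]
    d$..y.. <- y
    fit <- stats::lm(f, data = d[-miss, , drop = FALSE])
    y[miss] <- stats::predict(fit, newdata = d[miss, , drop = FALSE])
    data[[v]] <- y
  }
  attr(data, "imputed") <- imputed
  data
}

#' Modified Park test for the cost-variance family
#'
#' Regresses the log squared raw residuals on the log fitted means. The
#' slope estimates the power in var(y) proportional to mean^power; the
#' nearest integer names the canonical family: 0 gaussian, 1
#' poisson-like, 2 gamma, 3 inverse-gaussian.
#'
#' @param residuals raw residuals (y minus fitted).
#' @param fitted fitted means, strictly positive and non-constant.
#' @return list with `slope`, `se`, and `family` (character).
#' @export
modified_park_test <- function(residuals, fitted) {
  if (length(residuals) != length(fitted) || length(fitted) < 3) {
    stop("need >= 3 aligned residual/fitted pairs", call. = FALSE)
  }
  if (any(fitted <= 0)) {
    stop("fitted values must be strictly positive", call. = FALSE)
  }
  if (stats::sd(fitted) == 0) {
    stop("fitted values are constant; the Park regression is degenerate",
         call. = FALSE)
  }
  lr2 <- log(pmax(residuals^2, .Machine$double.eps))
  fit <- stats::lm(lr2 ~ log(fitted))
  slope <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  fam <- c("gaussian", "poisson", "gamma", "inverse_gaussian")
  idx <- min(max(round(slope), 0), 3) + 1
  list(slope = slope, se = se, family = fam[idx])
}

#' Fit the cost equation
#'
#' Generalized linear model with identity link for per-participant
#' costs, gamma family by default (skewed costs, additive covariate
#' effects), adjusted for the configured baseline covariates. The arm
#' coefficient is the adjusted incremental cost. Because the gamma
#' likelihood is undefined at zero, zero costs are floored at a small
#' positive value; if more than `max_zero_prop` of the responses are
#' zero the fit falls back to the gaussian family. `family = "auto"`
#' picks the family by the modified Park test on a preliminary
#' least-squares fit.
#'
#' @param data analysis data.frame with an `arm` column coded 0/1.
#' @param response name of the cost column.
#' @param covariates baseline adjustment columns (default age and
#'   baseline depressive-symptom severity).
#' @param family `"gamma"`, `"gaussian"`, or `"auto"`.
#' @param zero_floor floor applied to zero costs under gamma (EUR).
#' @param max_zero_prop zero fraction above which gaussian is used.
#' @return list with `fit`, `arm_effect`, `family_used`.
#' @export
fit_cost_model <- function(data, response = "cost",
                           covariates = c("age", "baseline_depression"),
                           family = c("gamma", "gaussian", "auto"),
                           zero_floor = 0.01, max_zero_prop = 0.2) {
  family <- match.arg(family)
  f <- stats::reformulate(c("arm", covariates), response = response)
  y <- data[[response]]
  if (family == "auto") {
    prelim <- stats::lm(f, data = data)
    ft <- stats::fitted(prelim)
    family <- if (all(ft > 0) && stats::sd(ft) > 0 &&
                  modified_park_test(stats::residuals(prelim), ft)$family == "gamma")
      "gamma" else "gaussian"
  }
  if (family == "gamma" && mean(y <= 0) > max_zero_prop) family <- "gaussian"
  if (family == "gaussian") {
    fit <- stats::lm(f, data = data)
  } else {
    d <- data
    d[[response]] <- pmax(y, zero_floor)
    start <- stats::coef(stats::lm(f, data = d))
    fit <- tryCatch(
      stats::glm(f, data = d, family = stats::Gamma(link = "identity"),
                 start = start, control = stats::glm.control(maxit = 100)),
      error = function(e) {
        stop(sprintf("gamma-identity cost model failed to converge: %s",
                     conditionMessage(e)), call. = FALSE)
      })
    if (!fit$converged) {
      stop("gamma-identity cost model did not converge within 100 iterations",
           call. = FALSE)
    }
  }
  list(fit = fit, arm_effect = unname(stats::coef(fit)["arm"]),
       family_used = family)
}

#' Fit the effect equation
#'
#' Ordinary least squares for the health effect: symptom-free status as
#' a 0/1 response (arm coefficient = adjusted risk difference) or QALYs
#' adjusted for baseline utility.
#'
#' @param data analysis data.frame with an `arm` column coded 0/1.
#' @param response name of the effect column.
#' @param covariates baseline adjustment columns (e.g. `"utility_t0"`
#'   for QALYs; none for symptom-free status).
#' @return list with `fit` and `arm_effect`.
#' @export
fit_effect_model <- function(data, response = "effect",
                             covariates = character(0)) {
  f <- stats::reformulate(c("arm", covariates), response = response)
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("effect model design is rank-deficient (collinear covariates)",
         call. = FALSE)
  }
  list(fit = fit, arm_effect = unname(stats::coef(fit)["arm"]))
}

# FGLS core on prebuilt design matrices; iterates residual-covariance
# and coefficient updates to convergence
sur_core <- function(X1, y1, X2, y2, tol = 1e-10, max_iter = 100) {
  n <- length(y1)
  b1 <- solve(crossprod(X1), crossprod(X1, y1))
  b2 <- solve(crossprod(X2), crossprod(X2, y2))
  X12 <- crossprod(X1, X2)
  X11 <- crossprod(X1)
  X22 <- crossprod(X2)
  scale1 <- mean(y1^2) + 1
  scale2 <- mean(y2^2) + 1
  for (it in seq_len(max_iter)) {
    r1 <- y1 - X1 %*% b1
    r2 <- y2 - X2 %*% b2
    S <- crossprod(cbind(r1, r2)) / n
    # perfect fit in either equation: GLS weighting is undefined but the
    # OLS solution is exact, so return it (degenerate, e.g. duplicated rows)
    if (S[1, 1] < 1e-20 * scale1 || S[2, 2] < 1e-20 * scale2) {
      return(list(b1 = drop(b1), b2 = drop(b2), sigma = S, resid_cor = 0))
    }
    if (det(S) <= 1e-12 * S[1, 1] * S[2, 2]) {
      stop("singular residual covariance in SUR fit", call. = FALSE)
    }
    Si <- solve(S)
    A <- rbind(cbind(Si[1, 1] * X11, Si[1, 2] * X12),
               cbind(Si[2, 1] * t(X12), Si[2, 2] * X22))
    rhs <- c(Si[1, 1] * crossprod(X1, y1) + Si[1, 2] * crossprod(X1, y2),
             Si[2, 1] * crossprod(X2, y1) + Si[2, 2] * crossprod(X2, y2))
    b <- solve(A, rhs)
    p1 <- ncol(X1)
    b1_new <- b[seq_len(p1)]
    b2_new <- b[-seq_len(p1)]
    delta <- max(abs(c(b1_new - b1, b2_new - b2)))
    b1 <- matrix(b1_new); b2 <- matrix(b2_new)
    if (delta < tol * (1 + max(abs(b)))) break
  }
  r1 <- y1 - X1 %*% b1
  r2 <- y2 - X2 %*% b2
  S <- crossprod(cbind(r1, r2)) / n
  rho <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  list(b1 = drop(b1), b2 = drop(b2), sigma = S, resid_cor = rho)
}

#' Seemingly unrelated regressions for the cost and effect equations
#'
#' Joint feasible-generalized-least-squares fit of the two-equation
#' system (cost and effect), allowing cross-equation residual
#' correlation. With identical regressor sets in both equations the
#' estimates coincide with per-equation least squares; with different
#' regressors the cross-equation correlation is exploited for
#' efficiency.
#'
#' @param data analysis data.frame with an `arm` column coded 0/1.
#' @param cost_formula,effect_formula model formulas, e.g.
#'   `cost ~ arm + age + baseline_depression` and
#'   `effect ~ arm + utility_t0`.
#' @param tol,max_iter FGLS convergence controls.
#' @return object of class `sur_fit`: coefficient vectors `coef_cost`
#'   and `coef_effect`, the residual covariance `sigma`, the residual
#'   correlation `resid_cor`, and the arm coefficients `delta_cost` and
#'   `delta_effect`.
#' @export
sur_fit <- function(data, cost_formula, effect_formula,
                    tol = 1e-10, max_iter = 100) {
  X1 <- stats::model.matrix(cost_formula, data)
  X2 <- stats::model.matrix(effect_formula, data)
  y1 <- as.numeric(data[[all.vars(cost_formula)[1]]])
  y2 <- as.numeric(data[[all.vars(effect_formula)[1]]])
  core <- sur_core(X1, y1, X2, y2, tol, max_iter)
  names(core$b1) <- colnames(X1)
  names(core$b2) <- colnames(X2)
  structure(list(coef_cost = core$b1, coef_effect = core$b2,
                 sigma = core$sigma, resid_cor = core$resid_cor,
                 delta_cost = unname(core$b1["arm"]),
                 delta_effect = unname(core$b2["arm"])),
            class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat("Seemingly unrelated regressions (FGLS)\n")
  cat(sprintf("  incremental cost:   %10.2f\n", x$delta_cost))
  cat(sprintf("  incremental effect: %10.4f\n", x$delta_effect))
  cat(sprintf("  residual correlation: %.3f\n", x$resid_cor))
  invisible(x)
}

#' Nonparametric bootstrap of the SUR incremental cost/effect pair
#'
#' Resamples participants with replacement (the participant is the
#' resampling unit), refits the two-equation system on each resample and
#' collects the arm-coefficient pairs. Replicates whose fit fails (e.g.
#' a resample missing one arm or with a singular design) are redrawn so
#' the replicate count stays exactly `B`; more than `max_fail_prop * B`
#' redraws raise an error.
#'
#' @param data analysis data.frame with an `arm` column coded 0/1.
#' @param cost_formula,effect_formula as in [sur_fit()].
#' @param B number of bootstrap replicates (default 2500, minimum 100).
#' @param seed integer seed; the cloud is reproducible given the seed.
#' @param max_fail_prop maximum tolerated fraction of failed draws.
#' @return object of class `sur_cloud`: `pairs` (data.frame
#'   `delta_cost`, `delta_effect` with `B` rows), `point_estimate` (the
#'   full-sample [sur_fit()]), `B`, `seed`, `n_redrawn`.
#' @export
bootstrap_sur <- function(data, cost_formula, effect_formula,
                          B = 2500, seed = 1L, max_fail_prop = 0.05) {
  if (B < 100) stop("'B' must be at least 100", call. = FALSE)
  point <- sur_fit(data, cost_formula, effect_formula)
  X1 <- stats::model.matrix(cost_formula, data)
  X2 <- stats::model.matrix(effect_formula, data)
  y1 <- as.numeric(data[[all.vars(cost_formula)[1]]])
  y2 <- as.numeric(data[[all.vars(effect_formula)[1]]])
  arm_col1 <- match("arm", colnames(X1))
  arm_col2 <- match("arm", colnames(X2))
  n <- nrow(X1)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  dc <- numeric(B); de <- numeric(B)
  n_redrawn <- 0L
  max_fail <- ceiling(max_fail_prop * B)
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      sur_core(X1[idx, , drop = FALSE], y1[idx],
               X2[idx, , drop = FALSE], y2[idx]),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_fail) {
        stop(sprintf(paste0("bootstrap aborted: %d failed replicates ",
                            "(> %.0f%% of B = %d); check the design for ",
                            "near-singularity"),
                     n_redrawn, 100 * max_fail_prop, B), call. = FALSE)
      }
      next
    }
    dc[b] <- fit$b1[arm_col1]
    de[b] <- fit$b2[arm_col2]
    b <- b + 1L
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  structure(list(pairs = data.frame(delta_cost = dc, delta_effect = de),
                 point_estimate = point, B = B, seed = as.integer(seed),
                 n_redrawn = n_redrawn),
            class = "sur_cloud")
}

#' @export
print.sur_cloud <- function(x, ...) {
  cat(sprintf("Bootstrap cloud: %d replicates (seed %d, %d redrawn)\n",
              x$B, x$seed, x$n_redrawn))
  cat(sprintf("  mean incremental cost %0.2f, mean incremental effect %0.4f\n",
              mean(x$pairs$delta_cost), mean(x$pairs$delta_effect)))
  invisible(x)
}

#' Leave-one-out (jackknife) SUR arm coefficients
#'
#' Used to estimate the acceleration constant of BCa intervals.
#'
#' @inheritParams bootstrap_sur
#' @return matrix with `n` rows and columns `delta_cost`, `delta_effect`.
#' @export
jackknife_sur <- function(data, cost_formula, effect_formula) {
  X1 <- stats::model.matrix(cost_formula, data)
  X2 <- stats::model.matrix(effect_formula, data)
  y1 <- as.numeric(data[[all.vars(cost_formula)[1]]])
  y2 <- as.numeric(data[[all.vars(effect_formula)[1]]])
  a1 <- match("arm", colnames(X1)); a2 <- match("arm", colnames(X2))
  n <- nrow(X1)
  out <- matrix(NA_real_, n, 2,
                dimnames = list(NULL, c("delta_cost", "delta_effect")))
  for (i in seq_len(n)) {
    fit <- tryCatch(sur_core(X1[-i, , drop = FALSE], y1[-i],
                             X2[-i, , drop = FALSE], y2[-i]),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      out[i, 1] <- fit$b1[a1]
      out[i, 2] <- fit$b2[a2]
    }
  }
  out
}

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' BCa interval of Efron: the bias correction z0 comes from the fraction
#' of replicates below the full-sample point estimate, the acceleration
#' from the skewness of jackknife leave-one-out estimates, and the
#' endpoints are replicate quantiles at the adjusted levels. With zero
#' bias and zero acceleration the interval reduces exactly to the
#' percentile interval.
#'
#' @param replicates numeric vector of bootstrap replicates (>= 100).
#' @param point_estimate full-sample point estimate.
#' @param jackknife_estimates leave-one-out estimates (optional; if
#'   `NULL` the acceleration is 0).
#' @param level confidence level in (0, 1), default 0.95.
#' @return numeric vector `c(lower, upper)` with attributes `z0` and
#'   `acceleration`.
#' @export
bca_ci <- function(replicates, point_estimate, jackknife_estimates = NULL,
                   level = 0.95) {
  replicates <- replicates[!is.na(replicates)]
  B <- length(replicates)
  if (B < 100) stop("need at least 100 replicates", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  if (max(replicates) - min(replicates) < .Machine$double.eps * max(1, abs(point_estimate))) {
    warning("all bootstrap replicates identical; returning a degenerate interval")
    out <- c(point_estimate, point_estimate)
    attr(out, "z0") <- 0; attr(out, "acceleration") <- 0
    return(out)
  }
  frac <- (sum(replicates < point_estimate) +
             0.5 * sum(replicates == point_estimate)) / B
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(frac)
  a <- 0
  if (!is.null(jackknife_estimates)) {
    jk <- jackknife_estimates[!is.na(jackknife_estimates)]
    if (length(jk) >= 3) {
      d <- mean(jk) - jk
      denom <- 6 * sum(d^2)^1.5
      if (denom > 0) a <- sum(d^3) / denom
    }
  }
  alpha <- (1 - level) / 2
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  out <- unname(stats::quantile(replicates, c(adj(zl), adj(zu)), names = FALSE))
  attr(out, "z0") <- z0
  attr(out, "acceleration") <- a
  out
}
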