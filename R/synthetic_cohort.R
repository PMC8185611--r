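#' Generate a synthetic two-arm insomnia trial cohort
#'
#' Draws a cohort with the statistical structure the downstream economic
#' evaluation assumes: baseline covariates (age, depressive-symptom score,
#' gross daily wage), Insomnia Severity Index (ISI) scores at baseline,
#' posttreatment (8 weeks) and 6-month follow-up with arm-specific
#' remission probabilities, SF-6D utility trajectories rising linearly in
#' the intervention arm so the mean QALY gain equals
#' `params$qaly_gain_int`, and two-part-gamma cost components whose
#' costed means converge to `params$cost_component_means`.
#'
#' Resource-use quantities are back-derived from each participant's drawn
#' category cost and the unit prices in `table`, so costing the returned
#' records with the same table reproduces the drawn costs exactly.
#' Quantities are therefore continuous (window-level averages), not
#' integer counts. Totals are split over `params$n_windows` recall
#' windows; the intervention-programme fee is booked in window 1.
#'
#' Missing-at-random dropout at the configured rate is applied via
#' [apply_dropout()] unless `params$dropout_rate == 0`.
#'
#' @param params a [cohort_params()] object.
#' @param table a [unit_cost_table()] used to translate drawn category
#'   costs into resource-use quantities.
#' @return an object of class `ee_cohort`: a list with elements
#'   `participants` (one row per participant), `resource_use` (one row
#'   per participant per recall window) and `params`.
#' @examples
#' coh <- generate_cohort(cohort_params(seed = 42))
#' nrow(coh$participants)  # 128
#' @export
generate_cohort <- function(params = cohort_params(),
                            table = unit_cost_table()) {
  stopifnot(inherits(params, "cohort_params"))
  stopifnot(inherits(table, "unit_cost_table"))
  set.seed(params$seed)

  n <- params$n_per_arm
  N <- 2L * n
  arm <- rep(c("intervention", "control"), each = n)
  is_int <- arm == "intervention"

  age <- rtruncnorm(N, params$age_mean, params$age_sd, 21, 67)
  depression <- rtruncnorm(N, params$depression_mean, params$depression_sd, 0, 60)
  wage <- rtruncnorm(N, params$wage_mean, params$wage_sd, 50, Inf)

  # ISI: inclusion required clinically significant symptoms at baseline
  isi_t0 <- round(rtruncnorm(N, 19, 3.5, 15, 28))
  p_rem <- ifelse(is_int, params$p_remission_int, params$p_remission_ctr)
  remit <- stats::rbinom(N, 1L, p_rem) == 1L
  isi_t2 <- numeric(N)
  isi_t2[remit] <- round(rtruncnorm(sum(remit), 4.5, 1.8, 0, 7.49))
  isi_t2[!remit] <- round(rtruncnorm(sum(!remit),
                                     ifelse(is_int[!remit], 12, 16),
                                     3.5, 8, 28))
  isi_t1 <- round(pmin(28, pmax(0, (isi_t0 + isi_t2) / 2 + stats::rnorm(N, 0, 2))))

  # utilities: linear trajectory; slope chosen so the trapezoid QALY gain
  # over the 0.5-year horizon equals qaly_gain_int (integral of b*t over
  # [0, 0.5] is b/8)
  tms <- assessment_times()
  # upper truncation at 0.90 keeps intervention-arm trajectories clear of
  # the utility ceiling, so the mean QALY gain is not attenuated by clamping
  u0 <- rtruncnorm(N, params$utility_baseline_mean,
                   params$utility_baseline_sd, 0.30, 0.90)
  slope <- ifelse(is_int, 8 * params$qaly_gain_int, 0)
  u1 <- pmin(1, pmax(0, u0 + slope * tms[2] + stats::rnorm(N, 0, params$utility_noise_sd)))
  u2 <- pmin(1, pmax(0, u0 + slope * tms[3] + stats::rnorm(N, 0, params$utility_noise_sd)))

  # two-part gamma cost components (6-month totals, EUR)
  comp_names <- setdiff(names(params$cost_component_means), "intervention")
  costs <- matrix(0, N, length(comp_names), dimnames = list(NULL, comp_names))
  shape <- 1 / params$cost_cv^2
  for (cn in comp_names) {
    m <- params$cost_component_means[[cn]]
    mu <- ifelse(is_int, m[1], m[2])
    p0 <- params$zero_prob[[cn]]
    pos <- stats::rbinom(N, 1L, 1 - p0) == 1L & mu > 0
    mu_pos <- mu / (1 - p0)
    draw <- numeric(N)
    draw[pos] <- stats::rgamma(sum(pos), shape = shape,
                               scale = mu_pos[pos] / shape)
    costs[, cn] <- draw
  }
  iv <- params$cost_component_means$intervention
  intervention_cost <- ifelse(is_int, iv[1], iv[2])

  # back-derive resource use from drawn costs and unit prices
  pr <- table$prices
  mh_psychiatrist_share <- 0.5  # mental-health cost split across provider types
  ineff <- stats::rbeta(N, params$inefficiency_mean * 10,
                        (1 - params$inefficiency_mean) * 10)
  ineff <- pmin(0.95, pmax(0.05, ineff))
  cap_days <- 125  # workdays in the 6-month horizon
  ineff <- pmax(ineff, pmin(costs[, "presenteeism"] / (cap_days * wage), 0.95))
  pres_days <- pmin(costs[, "presenteeism"] / (ineff * wage), cap_days)

  use <- data.frame(
    id = seq_len(N),
    gp_visits = costs[, "gp"] / price_of(table, "gp_visit"),
    psychiatrist_sessions = mh_psychiatrist_share * costs[, "mental_health"] /
      price_of(table, "psychiatrist_session"),
    psychotherapist_sessions = (1 - mh_psychiatrist_share) * costs[, "mental_health"] /
      price_of(table, "psychotherapist_session"),
    inpatient_days_psychiatric = 0,
    inpatient_days_psychosomatic = 0,
    allied_health_contacts = costs[, "allied_health"] / price_of(table, "allied_health_contact"),
    medication_ddd = costs[, "medication"] / weighted_ddd_price(table)[1],
    informal_care_hours = costs[, "informal_care"] / price_of(table, "opportunity_cost_per_hour"),
    domestic_help_hours = costs[, "domestic_help"] / price_of(table, "replacement_cost_per_hour"),
    out_of_pocket = costs[, "out_of_pocket"],
    travel_km = costs[, "travel"] / price_of(table, "travel_per_km"),
    absenteeism_days = costs[, "absenteeism"] / wage,
    presenteeism_days = pres_days,
    inefficiency_score = ineff,
    presenteeism_recoverable_hours = params$hlq_fraction * pres_days * ineff *
      params$hours_per_workday
  )

  # split 6-month totals over recall windows
  W <- params$n_windows
  if (W == 1L) {
    shares <- matrix(1, N, 1)
  } else {
    raw <- matrix(stats::rgamma(N * W, shape = 5, scale = 1), N, W)
    shares <- raw / rowSums(raw)
  }
  quant_cols <- setdiff(names(use), c("id", "inefficiency_score"))
  resource_use <- do.call(rbind, lapply(seq_len(W), function(w) {
    uw <- use
    uw[quant_cols] <- uw[quant_cols] * shares[, w]
    uw$inefficiency_score <- use$inefficiency_score
    uw$window <- w
    uw
  }))
  resource_use <- resource_use[order(resource_use$id, resource_use$window),
                               c("id", "window", setdiff(names(use), "id"))]
  rownames(resource_use) <- NULL

  participants <- data.frame(
    id = seq_len(N), arm = arm,
    age = age, baseline_depression = depression, gross_daily_wage = wage,
    isi_t0 = isi_t0, isi_t1 = isi_t1, isi_t2 = isi_t2,
    utility_t0 = u0, utility_t1 = u1, utility_t2 = u2,
    intervention_cost = intervention_cost,
    completed_followup = TRUE, missing_fields = "",
    stringsAsFactors = FALSE
  )

  cohort <- structure(list(participants = participants,
                           resource_use = resource_use,
                           params = params),
                      class = "ee_cohort")
  if (params$dropout_rate > 0) {
    cohort <- apply_dropout(cohort, rate = params$dropout_rate,
                            seed = derive_seed(params$seed, 1L),
                            covariate = params$dropout_covariate,
                            coef = params$dropout_coef)
  }
  cohort
}

#' Assessment schedule in years since randomization
#'
#' Baseline, posttreatment (8 weeks) and 6-month follow-up.
#' @return numeric vector of length 3.
#' @export
assessment_times <- function() c(t0 = 0, t1 = 8 / 52, t2 = 0.5)

#' Apply missing-at-random dropout to a cohort
#'
#' Marks the 6-month follow-up fields (final ISI, final utility, and the
#' last recall window's resource use) of dropped participants as missing.
#' Baseline and posttreatment fields are never removed. The individual
#' dropout probability follows a logistic model in the standardized
#' baseline covariate, with the intercept solved so the marginal dropout
#' probability equals `rate` — a missing-at-random mechanism that the
#' imputation stage's dropout-predictor selection can detect.
#'
#' @param cohort an `ee_cohort`.
#' @param rate marginal dropout probability in \[0, 1\].
#' @param seed integer seed for the dropout draws.
#' @param covariate baseline column driving dropout (default `"age"`).
#' @param coef log-odds slope on the standardized covariate; 0 gives
#'   completely-at-random dropout.
#' @return the cohort with missingness flags and `NA` follow-up fields.
#' @export
apply_dropout <- function(cohort, rate, seed = 1L,
                          covariate = "age", coef = 0.5) {
  stopifnot(inherits(cohort, "ee_cohort"))
  stop_if_not_prob(rate, "rate")
  p <- cohort$participants
  if (!covariate %in% names(p)) {
    stop(sprintf("dropout covariate '%s' not found", covariate), call. = FALSE)
  }
  if (rate == 0) return(cohort)

  z <- as.numeric(scale(p[[covariate]]))
  if (anyNA(z) || stats::sd(p[[covariate]]) == 0) z <- rep(0, nrow(p))
  if (coef == 0 || all(z == 0)) {
    prob <- rep(rate, nrow(p))
  } else if (rate == 1) {
    prob <- rep(1, nrow(p))
  } else {
    a <- stats::uniroot(function(a) mean(stats::plogis(a + coef * z)) - rate,
                        c(-40, 40))$root
    prob <- stats::plogis(a + coef * z)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  drop <- stats::runif(nrow(p)) < prob
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  p$isi_t2[drop] <- NA_real_
  p$utility_t2[drop] <- NA_real_
  p$completed_followup[drop] <- FALSE
  p$missing_fields[drop] <- "isi_t2,utility_t2,resource_use_last_window"

  ru <- cohort$resource_use
  last_w <- max(ru$window)
  affected <- ru$id %in% p$id[drop] & ru$window == last_w
  quant_cols <- setdiff(names(ru), c("id", "window"))
  ru[affected, quant_cols] <- NA_real_

  cohort$participants <- p
  cohort$resource_use <- ru
  cohort
}

#' @export
print.ee_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Synthetic trial cohort: %d participants (%d per arm), %d recall window(s)\n",
              nrow(p), sum(p$arm == "intervention"), max(x$resource_use$window)))
  cat(sprintf("  follow-up completed: %d/%d (%.1f%%)\n",
              sum(p$completed_followup), nrow(p),
              100 * mean(p$completed_followup)))
  invisible(x)
}
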