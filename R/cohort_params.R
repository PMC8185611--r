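#' Parameters of the synthetic two-arm trial cohort
#'
#' Bundles everything the generator needs to emulate the study population:
#' two arms of `n_per_arm` employed schoolteachers with clinically
#' significant insomnia, arm-level remission probabilities at the 6-month
#' follow-up, SF-6D utility trajectories with a configurable QALY gain in
#' the intervention arm, skewed (two-part gamma) cost components per
#' category calibrated to the trial's printed arm means, and
#' missing-at-random dropout driven by a baseline covariate.
#'
#' Cost-component means are 6-month accumulated EUR per participant and
#' are supplied as a named list of `c(intervention, control)` pairs. The
#' intervention-programme fee is a fixed price, not a random draw.
#'
#' @param n_per_arm participants per arm (default 64).
#' @param p_remission_int,p_remission_ctr probability of symptom-free
#'   status (ISI < 8) at 6 months, by arm (defaults 0.42 and 0.06).
#' @param utility_baseline_mean,utility_baseline_sd truncated-normal
#'   parameters of the baseline SF-6D utility (defaults 0.70, 0.08).
#' @param qaly_gain_int mean QALY gain of the intervention arm over the
#'   0.5-year horizon, relative to control (default 0.019).
#' @param utility_noise_sd measurement noise on follow-up utilities.
#' @param cost_component_means named list, category -> c(mean EUR
#'   intervention arm, mean EUR control arm); see
#'   [default_cost_component_means()].
#' @param cost_cv coefficient of variation of the positive (gamma) part
#'   of each cost component (default 1).
#' @param zero_prob named vector of per-category probabilities of zero
#'   use over the horizon (two-part model); see Details.
#' @param dropout_rate marginal probability of missing the 6-month
#'   follow-up (default 0.12, i.e. ~88% completion).
#' @param dropout_covariate baseline field the dropout odds depend on
#'   (default `"age"`; MAR mechanism).
#' @param dropout_coef log-odds slope of dropout on the standardized
#'   covariate (default 0.5).
#' @param age_mean,age_sd,depression_mean,depression_sd,wage_mean,wage_sd
#'   baseline covariate distributions: age in years, depressive-symptom
#'   score (CES-D-like scale), gross daily wage in EUR/day.
#' @param inefficiency_mean mean of the Beta-distributed presenteeism
#'   inefficiency score (fraction of productivity lost on impaired days).
#' @param hlq_fraction ratio of recoverable (HLQ) presenteeism hours to
#'   the Osterhaus-equivalent hours; < 1 so the HLQ estimate is lower.
#' @param hours_per_workday paid hours per workday (for HLQ hours).
#' @param n_windows number of cost recall windows covering the 6-month
#'   horizon (default 2 x 3 months).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()], [apply_dropout()]
#' @export
cohort_params <- function(n_per_arm = 64,
                          p_remission_int = 0.42,
                          p_remission_ctr = 0.06,
                          utility_baseline_mean = 0.70,
                          utility_baseline_sd = 0.08,
                          qaly_gain_int = 0.019,
                          utility_noise_sd = 0.02,
                          cost_component_means = default_cost_component_means(),
                          cost_cv = 1,
                          zero_prob = default_zero_prob(),
                          dropout_rate = 0.12,
                          dropout_covariate = "age",
                          dropout_coef = 0.5,
                          age_mean = 48, age_sd = 10,
                          depression_mean = 18, depression_sd = 8,
                          wage_mean = 150, wage_sd = 30,
                          inefficiency_mean = 0.4,
                          hlq_fraction = 0.4,
                          hours_per_workday = 8,
                          n_windows = 2,
                          seed = 1L) {
  stop_if_not_prob(p_remission_int, "p_remission_int")
  stop_if_not_prob(p_remission_ctr, "p_remission_ctr")
  stop_if_not_prob(dropout_rate, "dropout_rate")
  stop_if_not_prob(utility_baseline_mean, "utility_baseline_mean")
  stop_if_not_prob(inefficiency_mean, "inefficiency_mean")
  if (!is.numeric(n_per_arm) || n_per_arm < 2) {
    stop("'n_per_arm' must be at least 2", call. = FALSE)
  }
  if (!is.numeric(cost_cv) || cost_cv <= 0) {
    stop("'cost_cv' must be positive", call. = FALSE)
  }
  if (!is.list(cost_component_means) || is.null(names(cost_component_means))) {
    stop("'cost_component_means' must be a named list of c(int, ctr) pairs",
         call. = FALSE)
  }
  for (nm in names(cost_component_means)) {
    v <- cost_component_means[[nm]]
    if (length(v) != 2 || anyNA(v) || any(v < 0)) {
      stop(sprintf("cost component '%s' must be two non-negative means", nm),
           call. = FALSE)
    }
  }
  missing_zp <- setdiff(setdiff(names(cost_component_means), "intervention"),
                        names(zero_prob))
  if (length(missing_zp) > 0) {
    zero_prob[missing_zp] <- 0  # default: always-positive component
  }
  if (any(zero_prob < 0 | zero_prob > 1)) {
    stop("'zero_prob' entries must be probabilities", call. = FALSE)
  }
  if (n_windows < 1) stop("'n_windows' must be >= 1", call. = FALSE)

  structure(list(
    n_per_arm = as.integer(n_per_arm),
    p_remission_int = p_remission_int,
    p_remission_ctr = p_remission_ctr,
    utility_baseline_mean = utility_baseline_mean,
    utility_baseline_sd = utility_baseline_sd,
    qaly_gain_int = qaly_gain_int,
    utility_noise_sd = utility_noise_sd,
    cost_component_means = cost_component_means,
    cost_cv = cost_cv,
    zero_prob = zero_prob,
    dropout_rate = dropout_rate,
    dropout_covariate = dropout_covariate,
    dropout_coef = dropout_coef,
    age_mean = age_mean, age_sd = age_sd,
    depression_mean = depression_mean, depression_sd = depression_sd,
    wage_mean = wage_mean, wage_sd = wage_sd,
    inefficiency_mean = inefficiency_mean,
    hlq_fraction = hlq_fraction,
    hours_per_workday = hours_per_workday,
    n_windows = as.integer(n_windows),
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Default 6-month cost-component means (EUR) by arm
#'
#' Arm-level means of the accumulated per-participant cost categories the
#' generator is calibrated to (intervention arm, control arm). The
#' intervention-programme fee (299 EUR) applies to the intervention arm
#' only and is fixed rather than sampled.
#'
#' @return named list, category -> c(intervention mean, control mean).
#' @export
default_cost_component_means <- function() {
  list(
    intervention  = c(299,    0),
    gp            = c(36,    51),
    mental_health = c(150,  163),
    medication    = c(2,      5),
    allied_health = c(105,  170),
    informal_care = c(884, 1260),
    domestic_help = c(310,  295),
    out_of_pocket = c(45,    73),
    travel        = c(8,     15),
    absenteeism   = c(1005, 1104),
    presenteeism  = c(1185, 1883)
  )
}

#' Default probabilities of zero resource use per cost category
#'
#' Two-part model: a category's 6-month cost is 0 with this probability
#' and otherwise gamma-distributed, reproducing the zero-heavy, skewed
#' shape of self-reported resource use.
#'
#' @return named numeric vector of probabilities.
#' @export
default_zero_prob <- function() {
  c(gp = 0.40, mental_health = 0.70, medication = 0.85,
    allied_health = 0.60, informal_care = 0.70, domestic_help = 0.70,
    out_of_pocket = 0.50, travel = 0.50, absenteeism = 0.50,
    presenteeism = 0.30)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  2 x %d participants; remission %0.2f vs %0.2f; QALY gain %0.3f\n",
              x$n_per_arm, x$p_remission_int, x$p_remission_ctr, x$qaly_gain_int))
  cat(sprintf("  dropout %0.2f (MAR on %s); cost CV %0.2f; %d recall window(s); seed %d\n",
              x$dropout_rate, x$dropout_covariate, x$cost_cv, x$n_windows, x$seed))
  invisible(x)
}
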