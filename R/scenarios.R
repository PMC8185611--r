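#' Configuration of one evaluation scenario
#'
#' One cell of the analysis grid: costing perspective, health outcome,
#' presenteeism valuation method, intervention-price multiplier, sample
#' definition, bootstrap size and seed.
#'
#' @param id short scenario identifier.
#' @param perspective `"societal"` (all cost categories) or
#'   `"public_health_care"` (direct medical only).
#' @param outcome `"qaly"` (cost-utility) or `"symptom_free"`
#'   (cost-effectiveness).
#' @param presenteeism_method `"osterhaus"` or `"hlq"`.
#' @param intervention_cost_multiplier positive factor on the programme
#'   fee (sensitivity: 0.5, 0.8, 1, 1.2, 1.5).
#' @param sample `"itt"` (intention-to-treat with regression imputation)
#'   or `"completers"` (drop participants with missing follow-up).
#' @param impute `NULL` (automatic: impute under ITT only) or logical;
#'   `TRUE` together with `sample = "completers"` is a configuration
#'   error.
#' @param B bootstrap replicates (default 2500, minimum 100).
#' @param seed integer seed for the bootstrap resamples.
#' @param lambdas willingness-to-pay grid; default chosen by `outcome`.
#' @param level confidence level (default 0.95).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(id = "main",
                            perspective = c("societal", "public_health_care"),
                            outcome = c("qaly", "symptom_free"),
                            presenteeism_method = c("osterhaus", "hlq"),
                            intervention_cost_multiplier = 1,
                            sample = c("itt", "completers"),
                            impute = NULL,
                            B = 2500, seed = 1L,
                            lambdas = NULL, level = 0.95) {
  perspective <- match.arg(perspective)
  outcome <- match.arg(outcome)
  presenteeism_method <- match.arg(presenteeism_method)
  sample <- match.arg(sample)
  if (intervention_cost_multiplier <= 0) {
    stop("'intervention_cost_multiplier' must be positive", call. = FALSE)
  }
  if (B < 100) stop("'B' must be at least 100", call. = FALSE)
  if (isTRUE(impute) && sample == "completers") {
    stop("conflicting configuration: imputation requested for a completers-only sample",
         call. = FALSE)
  }
  if (is.null(impute)) impute <- sample == "itt"
  structure(list(id = id, perspective = perspective, outcome = outcome,
                 presenteeism_method = presenteeism_method,
                 intervention_cost_multiplier = intervention_cost_multiplier,
                 sample = sample, impute = impute, B = as.integer(B),
                 seed = as.integer(seed),
                 lambdas = if (is.null(lambdas)) wtp_grid(outcome) else
                   wtp_grid(outcome, lambdas),
                 level = level),
            class = "scenario_config")
}

# analysis frame: one row per participant with the scenario's cost and
# effect plus the baseline adjustment covariates
build_analysis_data <- function(cohort, config, table = unit_cost_table()) {
  bd <- cost_breakdown(cohort, table,
                       presenteeism_method = config$presenteeism_method,
                       intervention_cost_multiplier = config$intervention_cost_multiplier)
  out <- cohort_outcomes(cohort)
  p <- cohort$participants
  data.frame(
    id = p$id,
    arm = as.integer(p$arm == "intervention"),
    age = p$age,
    baseline_depression = p$baseline_depression,
    utility_t0 = p$utility_t0,
    cost = aggregate_costs(bd, config$perspective),
    effect = if (config$outcome == "qaly") out$qaly else
      as.numeric(out$symptom_free),
    completed_followup = p$completed_followup,
    stringsAsFactors = FALSE
  )
}

scenario_formulas <- function(config) {
  list(cost = cost ~ arm + age + baseline_depression,
       effect = if (config$outcome == "qaly") effect ~ arm + utility_t0 else
         effect ~ arm)
}

#' Run one evaluation scenario end to end
#'
#' Applies the scenario's costing choices (perspective, presenteeism
#' method, intervention-price multiplier) and sample definition, handles
#' missing follow-up data (regression imputation under
#' intention-to-treat; case deletion for completers-only), fits the
#' full-sample SUR system and the gamma-identity cost model, bootstraps
#' the incremental cost/effect pairs, and derives the decision
#' analytics.
#'
#' @param cohort an `ee_cohort`.
#' @param config a [scenario_config()].
#' @param table a [unit_cost_table()].
#' @return an `ee_result` (see [evaluate_cloud()]) with additional
#'   fields `config`, `glm_cost_effect` (gamma-GLM adjusted incremental
#'   cost) and `n_imputed`.
#' @export
run_scenario <- function(cohort, config = scenario_config(),
                         table = unit_cost_table()) {
  stopifnot(inherits(cohort, "ee_cohort"), inherits(config, "scenario_config"))
  data <- build_analysis_data(cohort, config, table)

  n_imputed <- 0L
  if (config$sample == "completers") {
    data <- data[stats::complete.cases(data[c("cost", "effect")]), ]
  } else if (config$impute) {
    outcome_predictors <- c("age", "baseline_depression", "utility_t0")
    dropout_predictors <- select_dropout_predictors(
      transform(data, miss = !completed_followup),
      "miss", c("age", "baseline_depression", "utility_t0"))
    predictors <- c("arm", union(outcome_predictors, dropout_predictors))
    data <- regression_impute(data, c("cost", "effect"), predictors)
    n_imputed <- length(attr(data, "imputed")$cost)
  }

  fm <- scenario_formulas(config)
  cloud <- bootstrap_sur(data, fm$cost, fm$effect, B = config$B,
                         seed = config$seed)
  jack <- jackknife_sur(data, fm$cost, fm$effect)
  res <- evaluate_cloud(cloud, jackknife = jack, level = config$level,
                        lambdas = config$lambdas)
  res$glm_cost_effect <- tryCatch(
    fit_cost_model(data, family = "gamma")$arm_effect,
    error = function(e) NA_real_)
  res$config <- config
  res$n_imputed <- n_imputed
  res
}

#' The sensitivity-scenario grid
#'
#' The eleven sensitivity cells of the evaluation: from the societal
#' perspective the HLQ presenteeism variant, the four intervention-price
#' multipliers (0.8, 1.2, 0.5, 1.5) and the completers-only sample; from
#' the public-health-care perspective the four multipliers and the
#' completers-only sample.
#'
#' @param outcome health outcome used across the grid (default QALYs).
#' @param B bootstrap replicates per scenario.
#' @param seed master seed; per-scenario seeds are derived
#'   deterministically from it.
#' @param level confidence level.
#' @return list of [scenario_config()] objects with unique ids.
#' @export
scenario_grid <- function(outcome = "qaly", B = 2500, seed = 1L,
                          level = 0.95) {
  specs <- list(
    list(id = "societal_hlq", perspective = "societal",
         presenteeism_method = "hlq"),
    list(id = "societal_price_plus20", perspective = "societal",
         intervention_cost_multiplier = 1.2),
    list(id = "societal_price_plus50", perspective = "societal",
         intervention_cost_multiplier = 1.5),
    list(id = "societal_price_minus20", perspective = "societal",
         intervention_cost_multiplier = 0.8),
    list(id = "societal_price_minus50", perspective = "societal",
         intervention_cost_multiplier = 0.5),
    list(id = "societal_completers", perspective = "societal",
         sample = "completers"),
    list(id = "public_price_plus20", perspective = "public_health_care",
         intervention_cost_multiplier = 1.2),
    list(id = "public_price_plus50", perspective = "public_health_care",
         intervention_cost_multiplier = 1.5),
    list(id = "public_price_minus20", perspective = "public_health_care",
         intervention_cost_multiplier = 0.8),
    list(id = "public_price_minus50", perspective = "public_health_care",
         intervention_cost_multiplier = 0.5),
    list(id = "public_completers", perspective = "public_health_care",
         sample = "completers")
  )
  lapply(seq_along(specs), function(i) {
    args <- specs[[i]]
    args$outcome <- outcome
    args$B <- B
    args$seed <- derive_seed(seed, i)
    args$level <- level
    do.call(scenario_config, args)
  })
}

#' Run a matrix of scenarios
#'
#' Runs each scenario on the shared cohort and collects one summary row
#' per scenario in the shape of a sensitivity-analysis table:
#' incremental cost and effect with BCa intervals, the ICER (or
#' "dominant"), and the cost-effectiveness plane quadrant percentages.
#' Errors in a scenario are rethrown with the scenario id prefixed.
#'
#' @param cohort an `ee_cohort`.
#' @param configs list of [scenario_config()]s (ids must be unique),
#'   e.g. from [scenario_grid()].
#' @param table a [unit_cost_table()].
#' @return data.frame with one row per scenario; the full `ee_result`
#'   objects are attached as attribute `"results"`.
#' @export
run_matrix <- function(cohort, configs, table = unit_cost_table()) {
  ids <- vapply(configs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("scenario ids must be unique", call. = FALSE)
  results <- lapply(configs, function(cfg) {
    tryCatch(run_scenario(cohort, cfg, table),
             error = function(e) {
               stop(sprintf("scenario '%s': %s", cfg$id, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  names(results) <- ids
  rows <- lapply(results, function(r) {
    q <- attr(r$quadrants, "rounded")
    data.frame(
      id = r$config$id, perspective = r$config$perspective,
      outcome = r$config$outcome,
      presenteeism = r$config$presenteeism_method,
      multiplier = r$config$intervention_cost_multiplier,
      sample = r$config$sample,
      delta_cost = r$delta_cost,
      delta_cost_lo = r$delta_cost_ci[1], delta_cost_hi = r$delta_cost_ci[2],
      delta_effect = r$delta_effect,
      delta_effect_lo = r$delta_effect_ci[1],
      delta_effect_hi = r$delta_effect_ci[2],
      icer = ifelse(r$dominant, NA_real_, r$icer),
      icer_label = ifelse(r$dominant, "dominant",
                          sprintf("%0.0f", r$icer)),
      icer_lo = r$icer_ci[1], icer_hi = r$icer_ci[2],
      pct_ne = q[["NE"]], pct_nw = q[["NW"]],
      pct_se = q[["SE"]], pct_sw = q[["SW"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "results") <- results
  out
}
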