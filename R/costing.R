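#' Unit-cost table for valuing resource use
#'
#' Unit prices (EUR, indexed to the reference year with the consumer
#' price index factor) for the costed services, plus the
#' purchasing-power-parity (PPP) rate for pound sterling conversion, the
#' medication price list (EUR per defined daily dose, optionally split
#' into statutory and private prices) and the statutory-insurance
#' population share used to weight them. The intervention-programme fee
#' per participant is carried here as well so scenario runs can scale it.
#'
#' @param reference_year price year (default 2013).
#' @param index_factor consumer-price-index multiplier applied when
#'   indexing older prices to the reference year (default 1.04).
#' @param ppp_eur_to_gbp PPP rate, GBP per EUR (default 0.85).
#' @param prices named numeric vector of unit prices in EUR. Required
#'   keys: `gp_visit`, `internal_medicine`, `psychiatrist_session`,
#'   `psychotherapist_session`, `inpatient_day_psychiatric`,
#'   `inpatient_day_psychosomatic`, `travel_per_km`,
#'   `opportunity_cost_per_hour`, `replacement_cost_per_hour`,
#'   `allied_health_contact`.
#' @param medication_prices named list, agent -> price per defined daily
#'   dose: either a single EUR value or `c(statutory = , private = )`.
#' @param statutory_share fraction of the population with statutory
#'   insurance, used to weight statutory/private medication prices
#'   (default 0.89).
#' @param intervention_price programme fee per intervention-arm
#'   participant in EUR (default 299).
#' @return an object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(reference_year = 2013,
                            index_factor = 1.04,
                            ppp_eur_to_gbp = 0.85,
                            prices = c(
                              gp_visit = 20.92,
                              internal_medicine = 68.06,
                              psychiatrist_session = 46.55,
                              psychotherapist_session = 81.44,
                              inpatient_day_psychiatric = 335.52,
                              inpatient_day_psychosomatic = 306.41,
                              travel_per_km = 0.30,
                              opportunity_cost_per_hour = 23.10,
                              replacement_cost_per_hour = 18.33,
                              allied_health_contact = 25.00
                            ),
                            medication_prices = list(antidepressant = 0.50),
                            statutory_share = 0.89,
                            intervention_price = 299) {
  stop_if_negative(prices, "prices")
  stop_if_negative(intervention_price, "intervention_price")
  stop_if_not_prob(statutory_share, "statutory_share")
  if (!is.numeric(ppp_eur_to_gbp) || ppp_eur_to_gbp <= 0 || ppp_eur_to_gbp > 1.5) {
    stop("'ppp_eur_to_gbp' must be in (0, 1.5]", call. = FALSE)
  }
  if (!is.numeric(index_factor) || index_factor <= 0) {
    stop("'index_factor' must be positive", call. = FALSE)
  }
  structure(list(reference_year = reference_year,
                 index_factor = index_factor,
                 ppp_eur_to_gbp = ppp_eur_to_gbp,
                 prices = prices,
                 medication_prices = medication_prices,
                 statutory_share = statutory_share,
                 intervention_price = intervention_price),
            class = "unit_cost_table")
}

price_of <- function(table, key) {
  if (!key %in% names(table$prices)) {
    stop(sprintf("no unit price configured for service '%s'", key),
         call. = FALSE)
  }
  unname(table$prices[[key]])
}

# statutory-share weighted EUR per defined daily dose, one value per agent
weighted_ddd_price <- function(table) {
  vapply(table$medication_prices, function(pr) {
    if (length(pr) == 1) return(unname(pr))
    if (!all(c("statutory", "private") %in% names(pr))) {
      stop("medication price must be a single value or c(statutory=, private=)",
           call. = FALSE)
    }
    table$statutory_share * pr[["statutory"]] +
      (1 - table$statutory_share) * pr[["private"]]
  }, numeric(1))
}

#' Index a price to the reference year
#'
#' @param price_eur price in EUR (non-negative).
#' @param index_factor consumer-price-index multiplier (default 1.04).
#' @return `price_eur * index_factor`.
#' @export
index_price <- function(price_eur, index_factor = 1.04) {
  stop_if_negative(price_eur, "price_eur")
  if (any(index_factor <= 0)) stop("'index_factor' must be positive", call. = FALSE)
  price_eur * index_factor
}

#' Convert EUR to GBP at purchasing power parity
#'
#' Multiplies by the PPP rate and rounds for reporting: unit prices to
#' two decimals, aggregate costs to the nearest pound, ties away from
#' zero.
#'
#' @param amount_eur amount(s) in EUR.
#' @param ppp GBP per EUR (default 0.85).
#' @param kind `"unit"` (2 dp) or `"aggregate"` (whole pounds).
#' @return amount(s) in GBP.
#' @examples
#' convert_eur_to_gbp(20.92)                       # 17.78
#' convert_eur_to_gbp(4030, kind = "aggregate")    # 3426
#' @export
convert_eur_to_gbp <- function(amount_eur, ppp = 0.85,
                               kind = c("unit", "aggregate")) {
  kind <- match.arg(kind)
  if (any(ppp <= 0)) stop("'ppp' must be positive", call. = FALSE)
  round_half_up(amount_eur * ppp, digits = if (kind == "unit") 2 else 0)
}

#' Cost health-care resource use
#'
#' Multiplies service counts by their unit prices. Mental-health care
#' aggregates psychiatrist and psychotherapist sessions and inpatient
#' days in psychiatric and psychosomatic hospitals.
#'
#' @param use a data.frame (or coercible list) with columns `gp_visits`,
#'   `psychiatrist_sessions`, `psychotherapist_sessions`,
#'   `inpatient_days_psychiatric`, `inpatient_days_psychosomatic`,
#'   `allied_health_contacts`. Missing columns count as zero use.
#' @param table a [unit_cost_table()].
#' @return data.frame with EUR columns `gp`, `mental_health`,
#'   `allied_health`.
#' @export
cost_health_care <- function(use, table = unit_cost_table()) {
  use <- as.data.frame(use)
  get0c <- function(col) if (col %in% names(use)) use[[col]] else 0
  cnt <- function(col) { x <- get0c(col); stop_if_negative(x[!is.na(x)], col); x }
  data.frame(
    gp = cnt("gp_visits") * price_of(table, "gp_visit"),
    mental_health =
      cnt("psychiatrist_sessions") * price_of(table, "psychiatrist_session") +
      cnt("psychotherapist_sessions") * price_of(table, "psychotherapist_session") +
      cnt("inpatient_days_psychiatric") * price_of(table, "inpatient_day_psychiatric") +
      cnt("inpatient_days_psychosomatic") * price_of(table, "inpatient_day_psychosomatic"),
    allied_health = cnt("allied_health_contacts") * price_of(table, "allied_health_contact")
  )
}

#' Cost prescribed medication from defined daily doses
#'
#' Each agent's price per defined daily dose (DDD) is the
#' statutory-share weighted mean of its statutory and private prices
#' when both are configured, else the single listed price.
#'
#' @param ddd_by_agent named numeric vector, agent -> DDD consumed.
#' @param table a [unit_cost_table()].
#' @return total medication cost in EUR (scalar).
#' @export
cost_medication <- function(ddd_by_agent, table = unit_cost_table()) {
  if (length(ddd_by_agent) == 0) return(0)
  stop_if_negative(unlist(ddd_by_agent), "ddd_by_agent")
  agents <- names(ddd_by_agent)
  if (is.null(agents)) stop("'ddd_by_agent' must be named by agent", call. = FALSE)
  missing <- setdiff(agents, names(table$medication_prices))
  if (length(missing) > 0) {
    stop(sprintf("no medication price configured for agent(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  prices <- weighted_ddd_price(table)[agents]
  sum(unlist(ddd_by_agent) * prices)
}

#' Cost patient and family resources
#'
#' Travel is valued per kilometre; informal care at the opportunity-cost
#' rate; domestic help at the replacement-cost rate (the hourly gross
#' wage of domestic help); out-of-pocket expenses pass through. The
#' rate-to-category assignment is configurable.
#'
#' @param use data.frame with columns `travel_km`, `informal_care_hours`,
#'   `domestic_help_hours`, `out_of_pocket` (missing columns are zero).
#' @param table a [unit_cost_table()].
#' @param informal_care_rate,domestic_help_rate price keys used for the
#'   two hourly categories.
#' @return data.frame with EUR columns `informal_care`, `domestic_help`,
#'   `out_of_pocket`, `travel`.
#' @export
cost_patient_family <- function(use, table = unit_cost_table(),
                                informal_care_rate = "opportunity_cost_per_hour",
                                domestic_help_rate = "replacement_cost_per_hour") {
  use <- as.data.frame(use)
  get0c <- function(col) if (col %in% names(use)) use[[col]] else 0
  cnt <- function(col) { x <- get0c(col); stop_if_negative(x[!is.na(x)], col); x }
  data.frame(
    informal_care = cnt("informal_care_hours") * price_of(table, informal_care_rate),
    domestic_help = cnt("domestic_help_hours") * price_of(table, domestic_help_rate),
    out_of_pocket = cnt("out_of_pocket"),
    travel = cnt("travel_km") * price_of(table, "travel_per_km")
  )
}

#' Cost absenteeism by the human capital approach
#'
#' Lost workdays valued at the participant's gross daily wage.
#'
#' @param days workdays lost.
#' @param gross_daily_wage gross wage in EUR per day.
#' @return EUR cost, `days * gross_daily_wage`.
#' @export
cost_absenteeism <- function(days, gross_daily_wage) {
  stop_if_negative(days[!is.na(days)], "days")
  stop_if_negative(gross_daily_wage[!is.na(gross_daily_wage)], "gross_daily_wage")
  days * gross_daily_wage
}

#' Cost presenteeism by the Osterhaus method
#'
#' Workdays with reduced functioning weighted by the self-reported
#' inefficiency score (fraction of productivity lost on those days) and
#' valued at the gross daily wage.
#'
#' @param days_impaired workdays worked with reduced functioning.
#' @param inefficiency_score fraction of productivity lost, in \[0, 1\].
#' @param gross_daily_wage gross wage in EUR per day.
#' @return EUR cost, `days_impaired * inefficiency_score * gross_daily_wage`.
#' @export
cost_presenteeism_osterhaus <- function(days_impaired, inefficiency_score,
                                        gross_daily_wage) {
  stop_if_negative(days_impaired[!is.na(days_impaired)], "days_impaired")
  ok <- !is.na(inefficiency_score)
  if (any(inefficiency_score[ok] < 0 | inefficiency_score[ok] > 1)) {
    stop("'inefficiency_score' must be in [0, 1]", call. = FALSE)
  }
  days_impaired * inefficiency_score * gross_daily_wage
}

#' Cost presenteeism by the HLQ method
#'
#' Values only the production loss that is recoverable and not yet made
#' up for: hours still to recover times the gross hourly wage. Yields a
#' lower estimate than the Osterhaus method whenever recoverable hours
#' fall short of the full inefficiency-weighted impairment.
#'
#' @param hours_to_recover recoverable, not-yet-compensated hours.
#' @param gross_hourly_wage gross wage in EUR per hour.
#' @return EUR cost, `hours_to_recover * gross_hourly_wage`.
#' @export
cost_presenteeism_hlq <- function(hours_to_recover, gross_hourly_wage) {
  stop_if_negative(hours_to_recover[!is.na(hours_to_recover)], "hours_to_recover")
  stop_if_negative(gross_hourly_wage[!is.na(gross_hourly_wage)], "gross_hourly_wage")
  hours_to_recover * gross_hourly_wage
}

#' Per-participant cost breakdown by category
#'
#' Sums each participant's resource use over the recall windows and
#' values it with the unit-cost table. Participants with a missing
#' window (dropouts) get `NA` in every use-derived category. The
#' intervention fee can be scaled for sensitivity scenarios.
#'
#' @param cohort an `ee_cohort`.
#' @param table a [unit_cost_table()].
#' @param presenteeism_method `"osterhaus"` (impaired days weighted by
#'   inefficiency) or `"hlq"` (recoverable hours).
#' @param intervention_cost_multiplier positive factor applied to the
#'   intervention category only.
#' @param hours_per_workday used to derive the hourly wage from the
#'   daily wage for the HLQ method (default 8).
#' @return data.frame of class `cost_breakdown`: `id`, `arm`, and EUR
#'   columns `intervention`, `gp`, `mental_health`, `medication`,
#'   `allied_health`, `informal_care`, `domestic_help`, `out_of_pocket`,
#'   `travel`, `absenteeism`, `presenteeism`.
#' @export
cost_breakdown <- function(cohort, table = unit_cost_table(),
                           presenteeism_method = c("osterhaus", "hlq"),
                           intervention_cost_multiplier = 1,
                           hours_per_workday = 8) {
  stopifnot(inherits(cohort, "ee_cohort"))
  presenteeism_method <- match.arg(presenteeism_method)
  if (intervention_cost_multiplier <= 0) {
    stop("'intervention_cost_multiplier' must be positive", call. = FALSE)
  }
  p <- cohort$participants
  ru <- cohort$resource_use
  quant_cols <- setdiff(names(ru), c("id", "window", "inefficiency_score"))

  # 6-month totals; NA if any window missing
  agg <- stats::aggregate(ru[quant_cols], by = list(id = ru$id), FUN = sum)
  ineff <- stats::aggregate(list(inefficiency_score = ru$inefficiency_score),
                            by = list(id = ru$id),
                            FUN = function(x) x[1])
  agg <- merge(agg, ineff, by = "id")
  agg <- agg[match(p$id, agg$id), ]

  hc <- cost_health_care(agg, table)
  pf <- cost_patient_family(agg, table)
  med_price <- weighted_ddd_price(table)
  if (length(med_price) == 0) stop("no medication prices configured", call. = FALSE)
  medication <- agg$medication_ddd * med_price[[1]]
  absenteeism <- cost_absenteeism(agg$absenteeism_days, p$gross_daily_wage)
  presenteeism <- if (presenteeism_method == "osterhaus") {
    cost_presenteeism_osterhaus(agg$presenteeism_days, agg$inefficiency_score,
                                p$gross_daily_wage)
  } else {
    cost_presenteeism_hlq(agg$presenteeism_recoverable_hours,
                          p$gross_daily_wage / hours_per_workday)
  }

  out <- data.frame(
    id = p$id, arm = p$arm,
    intervention = p$intervention_cost * intervention_cost_multiplier,
    gp = hc$gp, mental_health = hc$mental_health, medication = medication,
    allied_health = hc$allied_health,
    informal_care = pf$informal_care, domestic_help = pf$domestic_help,
    out_of_pocket = pf$out_of_pocket, travel = pf$travel,
    absenteeism = absenteeism, presenteeism = presenteeism,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

cost_categories <- function() {
  list(direct_medical = c("intervention", "gp", "mental_health", "medication",
                          "allied_health"),
       patient_family = c("informal_care", "domestic_help", "out_of_pocket",
                          "travel"),
       productivity = c("absenteeism", "presenteeism"))
}

#' Aggregate a cost breakdown under an analytic perspective
#'
#' The societal perspective sums all categories (direct medical, patient
#' and family, productivity); the public-health-care perspective keeps
#' direct medical costs only (intervention, GP, mental health,
#' medication, allied health).
#'
#' @param breakdown a [cost_breakdown()] data.frame, or any data.frame
#'   carrying the category columns.
#' @param perspective `"societal"` or `"public_health_care"`.
#' @return numeric vector of per-participant EUR totals.
#' @export
aggregate_costs <- function(breakdown,
                            perspective = c("societal", "public_health_care")) {
  perspective <- match.arg(perspective)
  cats <- cost_categories()
  wanted <- if (perspective == "societal") unlist(cats) else cats$direct_medical
  missing <- setdiff(wanted, names(breakdown))
  if (length(missing) > 0) {
    stop(sprintf("cost breakdown lacks category column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rowSums(as.data.frame(breakdown)[wanted])
}

#' Arm-level summary of a cost breakdown
#'
#' Mean per-participant EUR by category and arm with normal-theory 95%
#' confidence intervals, plus block subtotals and the societal total —
#' the shape of the trial's cost table.
#'
#' @param breakdown a [cost_breakdown()].
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with one row per category/subtotal and columns
#'   `mean_intervention`, `lo_intervention`, `hi_intervention`,
#'   `mean_control`, `lo_control`, `hi_control`, `incremental`.
#' @export
summarize_costs <- function(breakdown, conf_level = 0.95) {
  cats <- cost_categories()
  df <- as.data.frame(breakdown)
  df$direct_medical <- rowSums(df[cats$direct_medical])
  df$patient_family <- rowSums(df[cats$patient_family])
  df$productivity <- rowSums(df[cats$productivity])
  df$total <- df$direct_medical + df$patient_family + df$productivity
  rows <- c(unlist(cats), "direct_medical", "patient_family", "productivity",
            "total")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  one_arm <- function(a) {
    sub <- df[df$arm == a, rows, drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    se <- apply(sub, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
    })
    data.frame(mean = m, lo = m - z * se, hi = m + z * se)
  }
  i <- one_arm("intervention"); ctl <- one_arm("control")
  data.frame(category = rows,
             mean_intervention = i$mean, lo_intervention = i$lo,
             hi_intervention = i$hi,
             mean_control = ctl$mean, lo_control = ctl$lo, hi_control = ctl$hi,
             incremental = i$mean - ctl$mean,
             row.names = NULL)
}
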