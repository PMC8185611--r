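test_that("price indexation is a guarded product", {
  expect_equal(index_price(100, 1.04), 104)
  expect_equal(index_price(0, 1.04), 0)
  # pre-index GP price recovers the indexed 20.92 at 2 dp
  expect_equal(round_half_up(index_price(20.1154, 1.04), 2), 20.92)
  expect_error(index_price(-1), "non-negative")
  expect_error(index_price(10, 0), "positive")
})

test_that("EUR to GBP conversion reproduces printed pairs", {
  expect_equal(convert_eur_to_gbp(20.92), 17.78)
  expect_equal(convert_eur_to_gbp(299, kind = "aggregate"), 254)
  expect_equal(convert_eur_to_gbp(335.52), 285.19)
  expect_equal(convert_eur_to_gbp(306.41), 260.45)
  expect_equal(convert_eur_to_gbp(23.10), 19.64)
  expect_equal(convert_eur_to_gbp(18.33), 15.58)
  expect_equal(convert_eur_to_gbp(0.30), 0.26)
})

test_that("currency conversion round-trips within rounding precision", {
  amounts <- c(0.5, 20.92, 299, 4030, 11285)
  for (r in c(0.85, 0.7, 1.1)) {
    back <- convert_eur_to_gbp(amounts, ppp = r) / r
    expect_true(all(abs(back - amounts) <= 0.005 / r + 1e-9))
  }
})

test_that("health care use is costed at unit prices", {
  expect_equal(cost_health_care(list(gp_visits = 3), default_table)$gp, 62.76)
  z <- cost_health_care(list(gp_visits = 0, psychiatrist_sessions = 0,
                             allied_health_contacts = 0), default_table)
  expect_true(all(unlist(z) == 0))
  mh <- cost_health_care(list(psychiatrist_sessions = 2,
                              psychotherapist_sessions = 1), default_table)
  expect_equal(mh$mental_health, 2 * 46.55 + 81.44)  # 174.54
  ip <- cost_health_care(list(inpatient_days_psychiatric = 2,
                              inpatient_days_psychosomatic = 1), default_table)
  expect_equal(ip$mental_health, 2 * 335.52 + 306.41)
  # unknown service key is a configuration error naming the key
  tab <- default_table
  tab$prices <- tab$prices[names(tab$prices) != "gp_visit"]
  expect_error(cost_health_care(list(gp_visits = 1), tab), "gp_visit")
})

test_that("medication is costed with statutory-share weighting", {
  expect_equal(cost_medication(c(), default_table), 0)
  tab <- unit_cost_table(medication_prices = list(zolpidem = 0.10))
  expect_equal(cost_medication(c(zolpidem = 30), tab), 3.00)
  tab2 <- unit_cost_table(
    medication_prices = list(zolpidem = c(statutory = 0.10, private = 0.20)),
    statutory_share = 0.89)
  expect_equal(cost_medication(c(zolpidem = 100), tab2),
               100 * (0.89 * 0.10 + 0.11 * 0.20))  # 11.10
  expect_error(cost_medication(c(unknown_agent = 5), default_table),
               "unknown_agent")
})

test_that("patient and family costs use the configured hourly rates", {
  pf <- cost_patient_family(list(travel_km = 100, informal_care_hours = 10,
                                 domestic_help_hours = 10, out_of_pocket = 12),
                            default_table)
  expect_equal(pf$travel, 30)
  expect_equal(pf$informal_care, 231)       # opportunity cost 23.10/h
  expect_equal(pf$domestic_help, 183.30)    # replacement cost 18.33/h
  expect_equal(pf$out_of_pocket, 12)
  # rate assignment is configurable
  swapped <- cost_patient_family(list(informal_care_hours = 10), default_table,
                                 informal_care_rate = "replacement_cost_per_hour")
  expect_equal(swapped$informal_care, 183.30)
})

test_that("productivity losses follow the human capital and Osterhaus rules", {
  expect_equal(cost_absenteeism(5, 150), 750)
  expect_equal(cost_absenteeism(0, 150), 0)
  expect_equal(cost_absenteeism(10.5, 123.40), 1295.70)
  expect_equal(cost_presenteeism_osterhaus(10, 0.3, 100), 300)
  expect_equal(cost_presenteeism_osterhaus(10, 0, 100), 0)
  expect_equal(cost_presenteeism_osterhaus(20, 0.45, 137.50), 1237.50)
  expect_error(cost_presenteeism_osterhaus(10, 1.2, 100), "\\[0, 1\\]")
  expect_equal(cost_presenteeism_hlq(0, 25), 0)
  expect_equal(cost_presenteeism_hlq(8, 25), 200)
})

test_that("HLQ presenteeism is lower than Osterhaus on generated cohorts", {
  coh <- small_cohort(seed = 81, dropout = 0)
  ost <- cost_breakdown(coh, presenteeism_method = "osterhaus")
  hlq <- cost_breakdown(coh, presenteeism_method = "hlq")
  for (a in c("intervention", "control")) {
    expect_lt(mean(hlq$presenteeism[hlq$arm == a]),
              mean(ost$presenteeism[ost$arm == a]))
  }
})

test_that("perspective aggregation is additive and monotone", {
  coh <- small_cohort(seed = 91, dropout = 0)
  bd <- cost_breakdown(coh)
  soc <- aggregate_costs(bd, "societal")
  pub <- aggregate_costs(bd, "public_health_care")
  expect_true(all(pub <= soc + 1e-9))
  direct <- rowSums(bd[c("intervention", "gp", "mental_health", "medication",
                         "allied_health")])
  pat <- rowSums(bd[c("informal_care", "domestic_help", "out_of_pocket",
                      "travel")])
  prod <- rowSums(bd[c("absenteeism", "presenteeism")])
  expect_equal(soc, direct + pat + prod)
  expect_equal(pub, direct)
  bd$intervention <- NULL
  expect_error(aggregate_costs(bd, "societal"), "intervention")
})

test_that("scaling every unit price scales costed totals", {
  coh <- small_cohort(seed = 95, dropout = 0)
  tab <- default_table
  k <- 1.7
  tab2 <- tab
  tab2$prices <- tab$prices * k
  tab2$medication_prices <- lapply(tab$medication_prices, function(p) p * k)
  bd1 <- cost_breakdown(coh, tab)
  bd2 <- cost_breakdown(coh, tab2)
  priced <- c("gp", "mental_health", "medication", "allied_health",
              "informal_care", "domestic_help", "travel")
  for (cl in priced) expect_equal(bd2[[cl]], k * bd1[[cl]])
  # intervention fee, out-of-pocket and wage-valued categories held fixed
  for (cl in c("intervention", "out_of_pocket", "absenteeism", "presenteeism")) {
    expect_equal(bd2[[cl]], bd1[[cl]])
  }
})

test_that("unit cost table validates its fields", {
  expect_error(unit_cost_table(ppp_eur_to_gbp = 2), "0, 1.5")
  expect_error(unit_cost_table(statutory_share = 1.5), "probability")
  expect_error(unit_cost_table(prices = c(gp_visit = -1)), "non-negative")
})
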