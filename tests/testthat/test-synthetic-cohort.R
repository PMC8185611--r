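test_that("default cohort has the right bookkeeping", {
  coh <- generate_cohort(cohort_params(seed = 5, dropout_rate = 0))
  p <- coh$participants
  expect_equal(nrow(p), 128)
  expect_equal(sum(p$arm == "intervention"), 64)
  expect_equal(sum(p$arm == "control"), 64)
  expect_true(all(p$completed_followup))
  expect_true(all(p$missing_fields == ""))
  expect_equal(nrow(coh$resource_use), 128 * 2)  # two recall windows
  expect_true(all(p$isi_t0 >= 0 & p$isi_t0 <= 28))
  expect_true(all(p$isi_t2 >= 0 & p$isi_t2 <= 28))
  ucols <- c("utility_t0", "utility_t1", "utility_t2")
  expect_true(all(as.matrix(p[ucols]) >= 0 & as.matrix(p[ucols]) <= 1))
  quant <- setdiff(names(coh$resource_use), c("id", "window"))
  expect_true(all(as.matrix(coh$resource_use[quant]) >= 0))
})

test_that("cohorts are reproducible under a seed and differ across seeds", {
  a <- generate_cohort(cohort_params(seed = 21))
  b <- generate_cohort(cohort_params(seed = 21))
  c <- generate_cohort(cohort_params(seed = 22))
  expect_identical(a$participants, b$participants)
  expect_identical(a$resource_use, b$resource_use)
  expect_false(identical(a$participants, c$participants))
})

test_that("remission proportions converge to the configured probabilities", {
  # pooled over independent cohorts so the binomial check is stable
  rates <- vapply(1:10, function(s) {
    coh <- generate_cohort(cohort_params(n_per_arm = 2000, dropout_rate = 0,
                                         seed = 30 + s))
    c(remission_rate(coh, "intervention"), remission_rate(coh, "control"))
  }, numeric(2))
  n_pool <- 10 * 2000
  expect_lt(abs(mean(rates[1, ]) - 0.42), 2 * sqrt(0.42 * 0.58 / n_pool))
  expect_lt(abs(mean(rates[2, ]) - 0.06), 2 * sqrt(0.06 * 0.94 / n_pool))
})

test_that("gamma cost-component arm means obey the law of large numbers", {
  coh <- generate_cohort(cohort_params(n_per_arm = 10000, dropout_rate = 0,
                                       seed = 41))
  bd <- cost_breakdown(coh)
  means <- default_cost_component_means()
  zp <- default_zero_prob()
  for (comp in c("informal_care", "gp", "absenteeism", "presenteeism")) {
    for (a in c("intervention", "control")) {
      m <- means[[comp]][if (a == "intervention") 1 else 2]
      # two-part variance: m^2 * ((1 + cv^2)/(1 - p0) - 1), cv = 1
      sdv <- m * sqrt(2 / (1 - zp[[comp]]) - 1)
      emp <- mean(bd[[comp]][bd$arm == a])
      expect_lt(abs(emp - m), 3 * sdv / sqrt(10000))
    }
  }
})

test_that("the generated QALY contrast converges to the configured gain", {
  coh <- generate_cohort(cohort_params(n_per_arm = 10000, dropout_rate = 0,
                                       seed = 51))
  out <- cohort_outcomes(coh)
  dq <- mean(out$qaly[out$arm == "intervention"]) -
    mean(out$qaly[out$arm == "control"])
  # variability dominated by baseline-utility spread; use the empirical SE
  se <- sqrt(var(out$qaly[out$arm == "intervention"]) / 10000 +
               var(out$qaly[out$arm == "control"]) / 10000)
  expect_lt(abs(dq - 0.019), 2 * se)
})

test_that("zero dropout leaves every record complete", {
  coh <- generate_cohort(cohort_params(seed = 6, dropout_rate = 0))
  expect_true(all(coh$participants$completed_followup))
  expect_true(all(coh$participants$missing_fields == ""))
  expect_false(anyNA(coh$participants$isi_t2))
  expect_false(anyNA(coh$resource_use))
})

test_that("dropout marks follow-up fields and hits the target rate on average", {
  base <- generate_cohort(cohort_params(seed = 61, dropout_rate = 0))

  # full dropout
  all_out <- apply_dropout(base, rate = 1, seed = 1)
  expect_true(all(!all_out$participants$completed_followup))
  expect_true(all(is.na(all_out$participants$isi_t2)))
  expect_true(all(is.na(all_out$participants$utility_t2)))
  # baseline fields untouched
  expect_identical(all_out$participants$isi_t0, base$participants$isi_t0)
  expect_identical(all_out$participants$utility_t0, base$participants$utility_t0)
  last_w <- max(all_out$resource_use$window)
  expect_true(all(is.na(all_out$resource_use$gp_visits[
    all_out$resource_use$window == last_w])))
  expect_false(anyNA(all_out$resource_use$gp_visits[
    all_out$resource_use$window < last_w]))

  # rate 0.117 on 128 records: mean completers near 113 across seeds
  completers <- vapply(1:200, function(s) {
    sum(apply_dropout(base, rate = 0.117, seed = s)$participants$completed_followup)
  }, numeric(1))
  expect_lt(abs(mean(completers) - 113), 1)
})

test_that("covariate-dependent dropout is recoverable by logistic regression", {
  coh <- generate_cohort(cohort_params(n_per_arm = 5000, dropout_rate = 0,
                                       seed = 71))
  coh <- apply_dropout(coh, rate = 0.5, seed = 2, covariate = "age", coef = 1)
  p <- coh$participants
  fit <- glm(!completed_followup ~ scale(age), family = binomial(), data = p)
  co <- summary(fit)$coefficients
  expect_gt(co[2, 1] / co[2, 2], 2)          # clearly nonzero slope
  expect_lt(abs(co[2, 1] - 1), 3 * co[2, 2]) # near the configured coefficient
})

test_that("invalid generator parameters are rejected", {
  expect_error(cohort_params(p_remission_int = 1.2), "probability")
  expect_error(cohort_params(dropout_rate = -0.1), "probability")
  expect_error(cohort_params(n_per_arm = 1), "at least 2")
  expect_error(cohort_params(cost_cv = 0), "positive")
  expect_error(cohort_params(cost_component_means = list(gp = c(-1, 5))),
               "non-negative")
  expect_error(apply_dropout(small_cohort(), rate = 2), "probability")
})
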