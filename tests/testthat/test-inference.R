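test_that("regression imputation reduces to the fitted line and is idempotent", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2.1, 3.9, 6.2, 8.0, NA))
  out <- regression_impute(d, vars = "y", predictors = "x")
  fit <- lm(y ~ x, data = d[1:4, ])
  expect_equal(out$y[5], unname(predict(fit, data.frame(x = 5))))
  expect_equal(attr(out, "imputed")$y, 5L)

  complete <- data.frame(x = 1:4, y = c(1, 2, 3, 4))
  expect_equal(regression_impute(complete, "y", "x")$y, complete$y)

  d$x[1:5] <- NA
  expect_error(regression_impute(d, "y", "x"), "entirely missing")
})

test_that("imputation under MAR dropout recovers the pre-dropout arm mean", {
  full <- generate_cohort(cohort_params(n_per_arm = 4000, dropout_rate = 0,
                                        seed = 111))
  out_full <- cohort_outcomes(full)
  truth <- mean(out_full$qaly[out_full$arm == "intervention"])

  dropped <- apply_dropout(full, rate = 0.35, seed = 3,
                           covariate = "age", coef = 1)
  out_d <- cohort_outcomes(dropped)
  d <- data.frame(arm = as.integer(out_d$arm == "intervention"),
                  age = dropped$participants$age,
                  utility_t0 = dropped$participants$utility_t0,
                  qaly = out_d$qaly)
  imp <- regression_impute(d, "qaly", c("arm", "age", "utility_t0"))
  est <- mean(imp$qaly[imp$arm == 1])
  se <- sd(out_full$qaly[out_full$arm == "intervention"]) / sqrt(4000)
  expect_lt(abs(est - truth), 2 * se)
})

test_that("dropout predictors are found when and only when they drive dropout", {
  coh <- generate_cohort(cohort_params(n_per_arm = 2000, dropout_rate = 0,
                                       seed = 115))
  coh <- apply_dropout(coh, rate = 0.4, seed = 4, covariate = "age", coef = 1.5)
  p <- coh$participants
  p$miss <- !p$completed_followup
  sel <- select_dropout_predictors(p, "miss",
                                   c("age", "baseline_depression", "utility_t0"))
  expect_true("age" %in% sel)
})

test_that("the modified Park test identifies the variance family", {
  set.seed(7)
  n <- 5000
  x <- runif(n, 0, 2)
  mu <- exp(1 + x)
  # variance proportional to mean^2 -> gamma
  yg <- rgamma(n, shape = 4, scale = mu / 4)
  pk <- modified_park_test(yg - mu, mu)
  expect_lt(abs(pk$slope - 2), 0.15)
  expect_equal(pk$family, "gamma")
  # homoskedastic gaussian -> slope near 0
  yn <- mu + rnorm(n)  # constant variance
  pk0 <- modified_park_test(yn - mu, mu)
  expect_lt(abs(pk0$slope), 0.15)
  expect_equal(pk0$family, "gaussian")
  expect_error(modified_park_test(rnorm(10), rep(2, 10)), "degenerate")
  expect_error(modified_park_test(rnorm(10), c(-1, rep(2, 9))), "positive")
})

test_that("cost and effect models recover known arm effects", {
  # gaussian, no covariates: arm coefficient equals the raw mean difference
  d <- data.frame(arm = rep(0:1, each = 50),
                  cost = c(rnorm(50, 500, 50), rnorm(50, 380, 50)))
  m <- fit_cost_model(d, covariates = character(0), family = "gaussian")
  expect_equal(m$arm_effect,
               mean(d$cost[d$arm == 1]) - mean(d$cost[d$arm == 0]))

  # gamma identity, parameter recovery at scale: configure the generator for
  # a known societal incremental cost of -900
  means <- default_cost_component_means()
  means$absenteeism <- c(1095, 1104)  # shifts the default total gap to -900
  coh <- generate_cohort(cohort_params(n_per_arm = 10000, dropout_rate = 0,
                                       cost_component_means = means, seed = 121))
  dat <- data.frame(arm = as.integer(coh$participants$arm == "intervention"),
                    age = coh$participants$age,
                    baseline_depression = coh$participants$baseline_depression,
                    cost = aggregate_costs(cost_breakdown(coh), "societal"))
  mg <- fit_cost_model(dat, family = "gamma")
  se <- summary(mg$fit)$coefficients["arm", 2]
  expect_lt(abs(mg$arm_effect - (-900)), 2 * se)

  # effect model: risk difference with a 0/1 response and no covariates
  de <- data.frame(arm = rep(0:1, each = 40),
                   effect = c(rbinom(40, 1, 0.1), rbinom(40, 1, 0.5)))
  me <- fit_effect_model(de)
  expect_equal(me$arm_effect,
               mean(de$effect[de$arm == 1]) - mean(de$effect[de$arm == 0]))

  # QALY recovery on the generator
  out <- cohort_outcomes(coh)
  dq <- data.frame(arm = dat$arm, utility_t0 = coh$participants$utility_t0,
                   effect = out$qaly)
  mq <- fit_effect_model(dq, covariates = "utility_t0")
  seq_ <- summary(mq$fit)$coefficients["arm", 2]
  expect_lt(abs(mq$arm_effect - 0.019), 2 * seq_)

  # collinear covariates are rejected
  dc <- data.frame(arm = rep(0:1, each = 10), effect = rnorm(20))
  dc$dup <- dc$arm
  expect_error(fit_effect_model(dc, covariates = "dup"), "collinear")
})

test_that("gamma cost model falls back to gaussian with many zero costs", {
  set.seed(9)
  d <- data.frame(arm = rep(0:1, each = 100),
                  cost = ifelse(runif(200) < 0.4, 0, rgamma(200, 2, 0.01)))
  m <- fit_cost_model(d, covariates = character(0), family = "gamma")
  expect_equal(m$family_used, "gaussian")
})

test_that("SUR equals per-equation OLS under identical regressors", {
  d <- sim_sur_data(400, rho = 0.6, seed = 13)
  f1 <- cost ~ arm + age
  f2 <- effect ~ arm + age
  s <- sur_fit(d, f1, f2)
  expect_equal(unname(s$coef_cost), unname(coef(lm(f1, d))), tolerance = 1e-8)
  expect_equal(unname(s$coef_effect), unname(coef(lm(f2, d))), tolerance = 1e-8)
})

test_that("SUR recovers the cross-equation residual correlation", {
  d <- sim_sur_data(5000, rho = 0.5, seed = 17)
  s <- sur_fit(d, cost ~ arm + age, effect ~ arm + utility_t0)
  se_rho <- (1 - 0.5^2) / sqrt(5000)
  expect_lt(abs(s$resid_cor - 0.5), 2 * se_rho)
  # with no true correlation, SUR stays close to per-equation OLS
  d0 <- sim_sur_data(5000, rho = 0, seed = 19)
  s0 <- sur_fit(d0, cost ~ arm + age, effect ~ arm + utility_t0)
  expect_lt(abs(s0$delta_cost - coef(lm(cost ~ arm + age, d0))["arm"]),
            0.01 * abs(s0$delta_cost))
  expect_lt(abs(s0$delta_effect -
                  coef(lm(effect ~ arm + utility_t0, d0))["arm"]),
            0.01 * abs(s0$delta_effect))
})

test_that("bootstrap clouds are sized, seeded and centred correctly", {
  d <- sim_sur_data(128, rho = 0.3, seed = 23)
  f1 <- cost ~ arm + age
  f2 <- effect ~ arm + utility_t0
  cl <- bootstrap_sur(d, f1, f2, B = 400, seed = 5)
  expect_equal(nrow(cl$pairs), 400)
  cl2 <- bootstrap_sur(d, f1, f2, B = 400, seed = 5)
  expect_identical(cl$pairs, cl2$pairs)
  cl3 <- bootstrap_sur(d, f1, f2, B = 400, seed = 6)
  expect_false(identical(cl$pairs, cl3$pairs))
  # cloud mean near the point estimate (within Monte-Carlo tolerance)
  expect_lt(abs(mean(cl$pairs$delta_cost) - cl$point_estimate$delta_cost),
            3 * sd(cl$pairs$delta_cost) / sqrt(400))
  expect_error(bootstrap_sur(d, f1, f2, B = 50, seed = 1), "at least 100")
})

test_that("degenerate cohorts give a point-mass cloud", {
  one_ctr <- data.frame(arm = 0, cost = 500, effect = 0.30)
  one_int <- data.frame(arm = 1, cost = 420, effect = 0.35)
  d <- rbind(one_ctr[rep(1, 30), ], one_int[rep(1, 30), ])
  cl <- bootstrap_sur(d, cost ~ arm, effect ~ arm, B = 200, seed = 2)
  expect_true(all(abs(cl$pairs$delta_cost - (-80)) < 1e-8))
  expect_true(all(abs(cl$pairs$delta_effect - 0.05) < 1e-8))
})

test_that("bootstrap dispersion shrinks like sqrt(k) under cohort duplication", {
  d <- sim_sur_data(128, rho = 0.3, seed = 29)
  k <- 4
  dk <- d[rep(seq_len(nrow(d)), k), ]
  f1 <- cost ~ arm + age
  f2 <- effect ~ arm + utility_t0
  s1 <- sd(bootstrap_sur(d, f1, f2, B = 600, seed = 7)$pairs$delta_cost)
  sk <- sd(bootstrap_sur(dk, f1, f2, B = 600, seed = 7)$pairs$delta_cost)
  ratio <- s1 / sk
  expect_gt(ratio, sqrt(k) * 0.8)
  expect_lt(ratio, sqrt(k) * 1.25)
})

test_that("BCa reduces to the percentile interval under zero bias and acceleration", {
  set.seed(31)
  reps <- rnorm(2500)
  pt <- median(reps)  # exactly half the replicates below -> z0 = 0
  ci <- bca_ci(reps, pt, jackknife_estimates = NULL, level = 0.95)
  expect_equal(as.numeric(ci), unname(quantile(reps, c(0.025, 0.975))),
               tolerance = 1e-10)
  expect_equal(attr(ci, "z0"), 0, tolerance = 1e-3)
  # large-sample standard normal draws bracket +/- 1.96
  expect_lt(abs(ci[1] + 1.96), 0.15)
  expect_lt(abs(ci[2] - 1.96), 0.15)
})

test_that("BCa matches an independent textbook computation on skewed replicates", {
  set.seed(37)
  reps <- rexp(20000, rate = 1)
  pt <- 1.02
  jk <- rexp(200, rate = 1)
  ci <- bca_ci(reps, pt, jk, level = 0.9)
  # independent computation, written out from the BCa definition
  z0 <- qnorm(mean(reps < pt))
  dbar <- mean(jk)
  a <- sum((dbar - jk)^3) / (6 * sum((dbar - jk)^2)^1.5)
  al <- pnorm(z0 + (z0 + qnorm(0.05)) / (1 - a * (z0 + qnorm(0.05))))
  au <- pnorm(z0 + (z0 + qnorm(0.95)) / (1 - a * (z0 + qnorm(0.95))))
  expect_equal(as.numeric(ci),
               unname(quantile(reps, c(al, au))), tolerance = 1e-6)
})

test_that("degenerate replicate sets yield a flagged point interval", {
  expect_warning(ci <- bca_ci(rep(5, 200), 5), "identical")
  expect_equal(as.numeric(ci), c(5, 5))
  expect_error(bca_ci(rnorm(50), 0), "100 replicates")
  expect_error(bca_ci(rnorm(200), 0, level = 1.2), "\\(0, 1\\)")
})
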