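# shared fixtures: small cohorts and hand-built clouds, all generated in code

default_table <- unit_cost_table()

small_cohort <- function(seed = 11, n = 64, dropout = 0.12, ...) {
  generate_cohort(cohort_params(n_per_arm = n, dropout_rate = dropout,
                                seed = seed, ...))
}

# hand-built bootstrap cloud wrapper so decision analytics can be tested
# without running the bootstrap
fake_cloud <- function(delta_cost, delta_effect,
                       point_cost = mean(delta_cost),
                       point_effect = mean(delta_effect)) {
  structure(list(
    pairs = data.frame(delta_cost = delta_cost, delta_effect = delta_effect),
    point_estimate = list(delta_cost = point_cost, delta_effect = point_effect),
    B = length(delta_cost), seed = 0L, n_redrawn = 0L
  ), class = "sur_cloud")
}

# two-arm analysis frame with known gaussian structure, for SUR tests
sim_sur_data <- function(n, rho = 0, beta_cost = -900, beta_eff = 0.02,
                         sd_cost = 800, sd_eff = 0.006, seed = 1) {
  set.seed(seed)
  arm <- rep(0:1, each = n / 2)
  age <- rnorm(n, 48, 10)
  utility_t0 <- rnorm(n, 0.7, 0.08)
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(
    arm = arm, age = age, baseline_depression = rnorm(n, 18, 8),
    utility_t0 = utility_t0,
    cost = 3000 + beta_cost * arm + 5 * age + sd_cost * z1,
    effect = 0.35 + beta_eff * arm + 0.45 * utility_t0 + sd_eff * z2
  )
}
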