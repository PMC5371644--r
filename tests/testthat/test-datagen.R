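# Generator calibration and simulation: variance-share recovery, sign
# structure, determinism, degenerate configurations.

test_that("calibration reproduces requested APC shares on generated data", {
  w <- probit_world() # default 70/20/10 shares, n = 20,000
  a <- attribution_shares(w$params, w$data)
  expect_equal(unname(a$shares[["age"]]), 0.70, tolerance = 0.02)
  expect_equal(unname(a$shares[["period"]]), 0.20, tolerance = 0.02)
  expect_equal(unname(a$shares[["cohort"]]), 0.10, tolerance = 0.02)
  expect_equal(unname(a$mediator_shares[["unmeasured"]]), 0.40, tolerance = 0.03)
  expect_equal(sum(a$shares), 1)
})

test_that("non-default shares are recovered within tolerance", {
  cfg <- scenario_config("simple", "probit",
    n = 40000, seed = 31,
    shares = c(0.6, 0.2, 0.2)
  )
  params <- calibrate(cfg)
  a <- attribution_shares(params, generate_apc_data(cfg, params))
  expect_equal(unname(a$shares), c(0.6, 0.2, 0.2), tolerance = 0.02)
})

test_that("a pure-age world has zero mediator path coefficients", {
  cfg <- scenario_config("simple", "probit",
    n = 1000, seed = 1,
    shares = c(1, 0, 0)
  )
  params <- calibrate(cfg)
  deltas <- vapply(params$mediators, `[[`, numeric(1), "delta")
  expect_true(all(deltas == 0))
  a <- attribution_shares(params, generate_apc_data(cfg, params))
  expect_equal(unname(a$shares[["period"]]), 0)
  expect_equal(params$theta_direct, 0)
})

test_that("mediator signs follow the period/outcome sign table", {
  for (v in c("probit", "logistic", "linear")) {
    params <- calibrate(scenario_config("simple", v, n = 100, seed = 1))
    sgn <- function(m, f) sign(params$mediators[[m]][[f]])
    # period -> mediator: unmeasured -, bmi +, smoking -, statin +
    expect_equal(sgn("unmeasured", "g_p"), -1)
    expect_equal(sgn("bmi", "g_p"), +1)
    expect_equal(sgn("smoking", "g_p"), -1)
    expect_equal(sgn("statin", "g_p"), +1)
    # mediator -> outcome: unmeasured +, bmi +, smoking +, statin -
    expect_equal(sgn("unmeasured", "delta"), +1)
    expect_equal(sgn("bmi", "delta"), +1)
    expect_equal(sgn("smoking", "delta"), +1)
    expect_equal(sgn("statin", "delta"), -1)
    # induced period -> outcome signs are the products: -, +, -, -
    prods <- vapply(
      params$mediators,
      function(m) sign(m$g_p * m$delta), numeric(1)
    )
    expect_equal(unname(prods), c(-1, +1, -1, -1))
  }
})

test_that("period transforms are monotone across the period index", {
  specs <- default_mediator_specs("probit")
  for (m in names(specs)) {
    h <- period_transform(specs[[m]], 5)
    expect_true(all(diff(h) > 0), info = m)
    expect_equal(mean(h), 0, tolerance = 1e-12)
    expect_equal(mean(h^2), 1, tolerance = 1e-12)
  }
})

test_that("generation is reproducible and the identity holds by construction", {
  cfg <- scenario_config("simple", "logistic", n = 2000, seed = 77)
  d1 <- generate_apc_data(cfg)
  d2 <- generate_apc_data(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_true(validate_identity(d1)$pass)
  expect_equal(nrow(d1), 2000L)
  cfg2 <- cfg
  cfg2$seed <- 78L
  expect_false(identical(
    as.data.frame(generate_apc_data(cfg2))$outcome, as.data.frame(d1)$outcome
  ))
})

test_that("genotype is ~50% prevalent and independent of age, period, cohort", {
  cfg <- scenario_config("confounding", "probit", n = 30000, seed = 13)
  dat <- generate_apc_data(cfg)
  expect_equal(mean(dat$genotype), 0.50, tolerance = 0.02)
  expect_lt(abs(cor(dat$genotype, dat$a_idx)), 0.02)
  expect_lt(abs(cor(dat$genotype, dat$p_idx)), 0.02)
  expect_lt(abs(cor(dat$genotype, dat$c_idx)), 0.02)
})

test_that("linear-variant outcome mean matches the analytic target mean", {
  w <- linear_world()
  lk_targets <- w$cfg$baseline_risk_targets
  target_curve <- seq(lk_targets[1], lk_targets[2], length.out = 11)
  expect_equal(mean(w$data$outcome), mean(target_curve), tolerance = 0.01)
  # realized outcome equals latent predictor plus noise: regression of the
  # outcome on the analytic latent predictor has slope ~1
  lp <- apcmech:::latent_outcome(w$params, as.data.frame(w$data))
  expect_equal(unname(coef(lm(w$data$outcome ~ lp))[2]), 1, tolerance = 0.02)
})

test_that("probit age-specific mortality rises from ~0.005 to ~0.20", {
  cfg <- scenario_config("simple", "probit", n = 60000, seed = 303)
  dat <- generate_apc_data(cfg)
  by_age <- tapply(dat$outcome, dat$a_idx, mean)
  expect_true(all(diff(by_age) > 0)) # monotone increasing in age category
  expect_equal(unname(by_age[1]), 0.005, tolerance = 0.5) # relative
  expect_equal(unname(by_age[11]), 0.20, tolerance = 0.15)
})

test_that("infeasible configurations are rejected", {
  expect_error(
    scenario_config("simple", "probit", shares = c(1, 0.2, 0.1)),
    "summing to 1"
  )
  expect_error(
    scenario_config("simple", "probit", shares = c(1.2, -0.1, -0.1)),
    "in \\[0,1\\]"
  )
  expect_error(
    scenario_config("simple", "probit",
      mediator_shares = c(unmeasured = 1, bmi = 1, smoking = 0, statin = 0)
    ),
    "summing to 1"
  )
  expect_error(
    calibrate(scenario_config("more_causes", "probit", shares = c(0.9, 0, 0.1))),
    "infeasible"
  )
  expect_error(generate_apc_data(list(scenario = "simple")), "scenario_config")
})

test_that("attribution refuses a mismatched params/dataset pair", {
  w <- probit_world()
  other <- calibrate(scenario_config("confounding", "probit", n = 100, seed = 1))
  expect_error(attribution_shares(other, w$data), "not generated under")
})
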