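# Monte Carlo front-door: mediator/outcome simulation, identifiability of the
# refit, equivalence with path tracing in linear settings, and support for
# logistic links and product terms.

test_that("zero-noise mediator simulation is exact; null logistic links give 0.5", {
  tf <- toy_fits(gamma = 0.5, delta = 0.4)
  f <- tf$mediator_fits[[1]]
  f$sigma <- 0
  draws <- data.frame(a_idx = 1, p_idx = c(1, 2), c_idx = 1)
  out <- simulate_mediators(list(f), draws, seed = 1)
  expect_equal(out$m1, c(0, 0.5)) # intercept 0, period2 coefficient 0.5

  fb <- f
  fb$kind <- "binary"
  fb$family <- "logistic"
  fb$coef <- c(`(Intercept)` = 0, period2 = 0)
  big <- data.frame(
    a_idx = 1, p_idx = rep(1:2, each = 20000), c_idx = 1
  )
  out <- simulate_mediators(list(fb), big, seed = 2)
  expect_equal(mean(out$m1), 0.5, tolerance = 3 * sqrt(0.25 / 40000))
})

test_that("binary mediator draws match the link-inverted mean", {
  w <- probit_world()
  f <- fit_mediator_models(w$data, "statin")[[1]]
  n <- 50000
  draws <- data.frame(
    a_idx = 1, p_idx = rep(1:5, length.out = n), c_idx = 1
  )
  out <- simulate_mediators(list(f), draws, seed = 3)
  for (k in c(1, 5)) {
    p_hat <- mean(out$statin[out$p_idx == k])
    lp <- f$coef["(Intercept)"] + if (k > 1) f$coef[paste0("period", k)] else 0
    p_true <- pnorm(unname(lp))
    expect_equal(p_hat, p_true,
      tolerance = 3 * sqrt(p_true * (1 - p_true) / (n / 5)) / p_true
    )
  }
})

test_that("period draws outside the fitted range are rejected", {
  tf <- toy_fits(0.5, 0.4)
  draws <- data.frame(a_idx = 1, p_idx = c(1, 3), c_idx = 1)
  expect_error(
    simulate_mediators(tf$mediator_fits, draws, 1),
    "outside the empirically observed"
  )
})

test_that("outcome simulation requires identity-breaking draws", {
  w <- linear_world()
  fits <- list(
    mediator_fits = fit_mediator_models(w$data),
    outcome_fit = fit_outcome_model(w$data)
  )
  # identity-constrained design: every record satisfies c = p - a + n_age
  grid <- expand.grid(a_idx = 1:11, p_idx = 1:5)
  grid$c_idx <- grid$p_idx - grid$a_idx + 11L
  grid <- simulate_mediators(fits$mediator_fits, grid, 1)
  expect_error(
    simulate_outcomes(fits$outcome_fit, grid, 1),
    "independent"
  )
})

test_that("zero-coefficient logistic outcomes average 0.5; zero-noise linear is exact", {
  sch <- apc_scheme(c(0, 10), c(2000, 2010), 5)
  ofit <- structure(
    list(
      family = "logistic", mediators = "m1", direct_dims = c("age", "cohort"),
      confounder = NULL, interactions = character(), scheme = sch, n = 10,
      coef = c(
        `(Intercept)` = 0, age2 = 0, cohort2 = 0, cohort3 = 0, m1 = 0
      ),
      vcov = NULL, sigma = NULL, converged = TRUE, separation = FALSE
    ),
    class = "outcome_fit"
  )
  draws <- expand.grid(a_idx = 1:2, p_idx = 1:2, c_idx = 1:3)
  draws <- draws[rep(seq_len(nrow(draws)), 4000), ]
  draws$m1 <- 0.3
  world <- simulate_outcomes(ofit, draws, seed = 4)
  expect_equal(mean(world$draws$y), 0.5, tolerance = 3 * sqrt(0.25 / nrow(draws)))

  olin <- ofit
  olin$family <- "linear"
  olin$sigma <- 0
  olin$coef <- c(`(Intercept)` = 1, age2 = 2, cohort2 = 0, cohort3 = 1, m1 = 10)
  world <- simulate_outcomes(olin, draws, seed = 5)
  expect_equal(
    world$draws$y,
    1 + 2 * (draws$a_idx == 2) + (draws$c_idx == 3) + 3
  )
})

test_that("the factorial draw design is balanced, independent and identity-free", {
  sch <- paper_scheme()
  mc <- mc_config(draws = 825 * 8, seed = 6)
  draws <- apcmech:::mc_draw_design(sch, mc)
  expect_equal(nrow(draws), 825 * 8)
  expect_equal(as.integer(table(draws$a_idx)), rep(825L * 8L / 11L, 11))
  # independence of the draws: age uncorrelated with period - cohort
  expect_lt(abs(cor(draws$a_idx, draws$p_idx - draws$c_idx)), 1e-10)
  expect_false(all(draws$c_idx == draws$p_idx - draws$a_idx + sch$n_age))
})

test_that("the simulated design restores the rank lost to the APC identity", {
  w <- linear_world()
  sch <- attr(w$data, "scheme")
  # identity-constrained real data: rank deficient by exactly 1
  X_real <- cbind(1, apcmech:::build_design(
    as.data.frame(w$data), c("age", "period", "cohort"),
    scheme = sch
  ))
  expect_equal(qr(X_real)$rank, ncol(X_real) - 1L)
  # independent draws: full rank
  draws <- apcmech:::mc_draw_design(sch, mc_config(draws = 5000, seed = 7))
  X_sim <- cbind(1, apcmech:::build_design(
    draws, c("age", "period", "cohort"),
    scheme = sch
  ))
  expect_equal(qr(X_sim)$rank, ncol(X_sim))
})

test_that("linear-setting estimates converge to path tracing as draws grow", {
  w <- linear_world()
  mfits <- fit_mediator_models(w$data)
  ofit <- fit_outcome_model(w$data)
  pt <- path_trace(mfits, ofit)
  mc_small <- apcmech:::mc_from_fits(mfits, ofit, mc_config(3e4, seed = 8))
  mc_large <- apcmech:::mc_from_fits(mfits, ofit, mc_config(3e5, seed = 8))
  err_small <- max(abs(mc_small$estimate - pt$estimate))
  err_large <- max(abs(mc_large$estimate - pt$estimate))
  expect_lt(err_large, 0.02)
  expect_lt(err_large, err_small) # Monte Carlo error shrinks with draws
})

test_that("doubling draws moves estimates by less than the Monte Carlo error bound", {
  w <- probit_world()
  est1 <- estimate_mcfrontdoor(w$data, mc = mc_config(1e5, seed = 9))
  est2 <- estimate_mcfrontdoor(w$data, mc = mc_config(2e5, seed = 10))
  nonref <- est1$category != 1
  d <- abs(est1$estimate - est2$estimate)[nonref]
  bound <- 4 * sqrt(est1$mc_se^2 + est2$mc_se^2)[nonref]
  expect_true(all(d <= pmax(bound, 0.02)))
})

test_that("reusing or regenerating the period draws gives the same estimates", {
  w <- linear_world()
  mfits <- fit_mediator_models(w$data)
  ofit <- fit_outcome_model(w$data)
  e1 <- apcmech:::mc_from_fits(mfits, ofit, mc_config(2e5, seed = 11))
  e2 <- apcmech:::mc_from_fits(
    mfits, ofit, mc_config(2e5, seed = 11, reuse_p = FALSE)
  )
  nonref <- e1$category != 1
  bound <- 4 * sqrt(e1$mc_se^2 + e2$mc_se^2)[nonref]
  expect_true(all(
    abs(e1$estimate - e2$estimate)[nonref] <= pmax(bound, 0.02)
  ))
})

test_that("logistic-variant estimation recovers the generator reference", {
  cfg <- scenario_config("simple", "logistic", n = 100000, seed = 406)
  params <- calibrate(cfg)
  dat <- generate_apc_data(cfg, params)
  est <- estimate_mcfrontdoor(dat, mc = mc_config(4e5, seed = 12))
  tru <- true_apc_effects(params, "mcfrontdoor",
    mc = mc_config(1.2e6, seed = 99)
  )
  # per-dimension average deviation small relative to the effect ranges;
  # the two oldest cohort categories are excluded: they exist only in the
  # sparsest corner of the design (youngest ages at the latest periods, where
  # mortality is lowest) and their single-replicate MLEs are unstable
  for (d in c("age", "period", "cohort")) {
    keep <- est$dimension == d &
      !(d == "cohort" & est$category >= 14)
    dev <- est$estimate[keep] - tru$estimate[keep]
    rng <- diff(range(tru$estimate[tru$dimension == d]))
    expect_lt(mean(abs(dev)), 0.08 * max(rng, 1))
  }
})

test_that("estimation without mediators is refused", {
  w <- probit_world()
  expect_error(
    estimate_mcfrontdoor(w$data, mediators = character()),
    "nothing to integrate"
  )
})

test_that("product terms are supported end to end", {
  w <- linear_world()
  tf <- params_to_fits(w$params)
  ofit <- tf$outcome_fit
  # inject a mediator x age product term into the generating outcome model
  ofit$interactions <- "unmeasured:age"
  for (k in 2:11) {
    ofit$coef[paste0("unmeasured:age", k)] <- 0.004 * (k - 1)
  }
  # generate identity-constrained records from the modified truth
  n <- 30000
  recs <- with_local_seed(21, {
    age <- runif(n, 40, 95)
    period <- runif(n, 1990, 2015)
    df <- cbind(
      data.frame(age = age, period = period),
      apc_categorize(age, period, w$params$scheme)
    )
    df
  })
  recs <- simulate_mediators(tf$mediator_fits, recs, seed = 22)
  X <- apcmech:::build_design(recs, c("age", "cohort"),
    mediators = names(w$params$mediators),
    scheme = w$params$scheme, interactions = "unmeasured:age"
  )
  recs$outcome <- with_local_seed(
    23,
    drop(cbind(1, X) %*% ofit$coef) + rnorm(n, 0, ofit$sigma)
  )
  dat <- apc_dataset(recs, w$params$scheme,
    mediators = names(w$params$mediators), variant = "linear"
  )
  # path tracing must refuse; the MC front-door proceeds
  mfits <- fit_mediator_models(dat)
  ofit_hat <- fit_outcome_model(dat, interactions = "unmeasured:age")
  expect_error(path_trace(mfits, ofit_hat), "product terms")
  est <- apcmech:::mc_from_fits(mfits, ofit_hat, mc_config(3e5, seed = 24))
  tru <- apcmech:::mc_from_fits(
    tf$mediator_fits, ofit, mc_config(1e6, seed = 25)
  )
  dev <- abs(est$estimate - tru$estimate)
  expect_lt(max(dev), 0.03) # marginal APC effects recovered
})

test_that("mcfrontdoor matches pathtrace on probit data with a confounder", {
  cfg <- scenario_config("confounding", "probit", n = 40000, seed = 505)
  params <- calibrate(cfg)
  dat <- generate_apc_data(cfg, params)
  exposures <- list(
    bmi = c("period", "genotype"), smoking = c("period", "genotype")
  )
  est <- estimate_mcfrontdoor(dat,
    exposures = exposures, confounder = "genotype",
    mc = mc_config(3e5, seed = 13)
  )
  expect_equal(attr(est, "estimator"), "mcfrontdoor")
  expect_true(all(est$estimate[est$category == 1] == 0))
  expect_equal(nrow(est), 11 + 5 + 15)
})
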