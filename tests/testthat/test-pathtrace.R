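# Path tracing: product-of-coefficients algebra, model fitting, refusals,
# delta-method SEs and the bootstrap.

test_that("a single pathway is the product of its two coefficients", {
  tf <- toy_fits(gamma = 0.5, delta = 0.4)
  est <- path_trace(tf$mediator_fits, tf$outcome_fit)
  per <- est[est$dimension == "period", ]
  expect_equal(per$estimate, c(0, 0.5 * 0.4))
  # age and cohort come straight from the outcome model
  expect_equal(est$estimate[est$dimension == "age"], c(0, 0.3))
  expect_equal(est$estimate[est$dimension == "cohort"], c(0, 0.1, 0.2))
  # reference categories are exactly zero
  expect_true(all(est$estimate[est$category == 1] == 0))
})

test_that("parallel pathways sum: 0.5*0.4 + (-0.6)*0.5 = -0.10", {
  tf <- toy_fits(gamma = 0.5, delta = 0.4, extra_mediator = c(-0.6, 0.5))
  est <- path_trace(tf$mediator_fits, tf$outcome_fit)
  expect_equal(
    est$estimate[est$dimension == "period" & est$category == 2], -0.10
  )
})

test_that("logistic fits and product terms are refused with guidance", {
  tf <- toy_fits(0.5, 0.4)
  tf$outcome_fit$family <- "logistic"
  expect_error(
    path_trace(tf$mediator_fits, tf$outcome_fit), "estimate_mcfrontdoor"
  )
  tf <- toy_fits(0.5, 0.4)
  names(tf$outcome_fit$coef)[2] <- "m1:age2"
  expect_error(path_trace(tf$mediator_fits, tf$outcome_fit), "product terms")
})

test_that("path tracing on linear models equals OLS on mediator-marginalized data", {
  # small-instance oracle: on an identity-free grid with each mediator
  # replaced by its model-implied mean, the period dummy coefficients of a
  # direct APC regression equal the summed path products exactly
  w <- linear_world()
  mfits <- fit_mediator_models(w$data)
  ofit <- fit_outcome_model(w$data)
  pt <- path_trace(mfits, ofit)
  grid <- expand.grid(a_idx = 1:11, p_idx = 1:5, c_idx = 1:15)
  for (f in mfits) {
    X <- build_mediator_mean <- cbind(
      1, apcmech:::make_dummies(grid$p_idx, 5, "period")
    )
    grid[[f$name]] <- drop(X %*% f$coef)
  }
  Xo <- cbind(1, apcmech:::build_design(
    grid, c("age", "cohort"), attr(w$data, "mediators"),
    scheme = w$params$scheme
  ))
  grid$y <- drop(Xo %*% ofit$coef)
  Xapc <- apcmech:::build_design(grid, c("age", "period", "cohort"),
    scheme = w$params$scheme
  )
  direct <- lm.fit(cbind(1, Xapc), grid$y)$coefficients
  for (k in 2:5) {
    expect_equal(
      unname(direct[paste0("period", k)]),
      pt$estimate[pt$dimension == "period" & pt$category == k],
      tolerance = 1e-10
    )
  }
  # and the direct age/cohort coefficients are untouched by marginalization
  expect_equal(
    unname(direct["age5"]), unname(ofit$coef["age5"]),
    tolerance = 1e-10
  )
})

test_that("linear-variant estimates recover the generator truth", {
  w <- linear_world()
  est <- estimate_pathtrace(w$data)
  tru <- true_apc_effects(w$params, "pathtrace")
  boot <- apc_bootstrap(
    apcmech:::apc_resample(w$data, seq_len(6000)),
    function(d) estimate_pathtrace(d),
    B = 60, seed = 5
  )
  # bootstrap SEs at n = 6000 bound the n = 20000 sampling error comfortably
  z <- abs(est$estimate - tru$estimate) / pmax(boot$se, 1e-12)
  expect_lt(stats::quantile(z, 0.9), 3)
  expect_lt(max(z), 4)
})

test_that("a mediator with no period dependence has null fitted coefficients", {
  w <- linear_world()
  dat <- w$data
  # break the period link by permuting the mediator column
  dat$unmeasured <- with_local_seed(1, sample(dat$unmeasured))
  f <- fit_mediator_models(dat, "unmeasured")[[1]]
  for (k in 2:5) {
    nm <- paste0("period", k)
    expect_lt(abs(f$coef[nm]) / sqrt(f$vcov[nm, nm]), 3.5)
  }
})

test_that("age coefficients in the more_causes BMI model are negative", {
  cfg <- scenario_config("more_causes", "probit", n = 30000, seed = 52)
  dat <- generate_apc_data(cfg)
  f <- fit_mediator_models(
    dat, "bmi",
    exposures = list(bmi = c("period", "age"))
  )[[1]]
  age_coefs <- f$coef[grep("^age", names(f$coef))]
  expect_length(age_coefs, 10L)
  expect_true(all(age_coefs < 0))
  # and they recover the generating age->BMI slope
  params <- attr(dat, "provenance")$params
  expect_equal(
    unname(age_coefs["age11"]), params$mediators$bmi$g_a * 10,
    tolerance = 0.1
  )
})

test_that("the outcome model has the advertised coefficient structure", {
  w <- probit_world()
  ofit <- fit_outcome_model(w$data)
  expect_equal(ofit$family, "probit")
  expect_length(ofit$coef, 1 + 10 + 14 + 4)
  expect_setequal(
    names(ofit$coef),
    c(
      "(Intercept)", paste0("age", 2:11), paste0("cohort", 2:15),
      "unmeasured", "bmi", "smoking", "statin"
    )
  )
  # mediator coefficients recover the generating deltas
  deltas <- vapply(w$params$mediators, `[[`, numeric(1), "delta")
  for (m in names(deltas)) {
    expect_equal(
      unname(ofit$coef[m]), unname(deltas[m]),
      tolerance = 4 * sqrt(ofit$vcov[m, m]) / abs(deltas[m])
    )
  }
})

test_that("rank-deficient designs are rejected with an informative error", {
  w <- linear_world()
  expect_error(
    fit_outcome_model(w$data, direct_dims = c("age", "period", "cohort")),
    "singular"
  )
})

test_that("delta-method SE matches its closed form and the bootstrap", {
  expect_equal(delta_method_se(0.5, 0.4, 0.1, 0.2),
    sqrt(0.25 * 0.04 + 0.16 * 0.01),
    tolerance = 1e-12
  )
  # one SE zero: only the other term survives
  expect_equal(delta_method_se(0.5, 0.4, 0, 0.2), sqrt(0.25 * 0.04))
  expect_equal(delta_method_se(0.5, 0.4, 0.1, 0), sqrt(0.16 * 0.01))

  # agreement with a bootstrap oracle on a single linear pathway
  w <- linear_world()
  dat <- apcmech:::apc_resample(w$data, seq_len(10000))
  dat <- drop_mediators(dat, c("bmi", "smoking", "statin"))
  mfit <- fit_mediator_models(dat, "unmeasured")[[1]]
  ofit <- fit_outcome_model(dat, "unmeasured")
  dm <- delta_method_se_path(mfit, ofit)
  boot <- apc_bootstrap(
    dat, function(d) estimate_pathtrace(d, "unmeasured"),
    B = 400, seed = 77
  )
  bse <- boot$se[boot$dimension == "period"]
  for (k in 2:5) {
    expect_equal(dm$se[k], bse[k], tolerance = 0.15)
  }
  # refusal outside the single linear pathway setting
  expect_error(
    delta_method_se_path(
      fit_mediator_models(w$data, "smoking",
        variant = "probit"
      )[[1]],
      ofit
    ),
    "linear models only"
  )
})

test_that("bootstrap draws are seed-reproducible; a degenerate estimator has SE 0", {
  w <- linear_world()
  dat <- apcmech:::apc_resample(w$data, seq_len(3000))
  est <- function(d) estimate_pathtrace(d)
  b1 <- apc_bootstrap(dat, est, B = 8, seed = 42)
  b2 <- apc_bootstrap(dat, est, B = 8, seed = 42)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  b3 <- apc_bootstrap(dat, est, B = 8, seed = 43)
  expect_false(identical(b1$se, b3$se))
  # an estimator invariant to resampling (as on a dataset of identical
  # records) has zero bootstrap SE and zero-width intervals
  const <- function(d) est(apcmech:::apc_resample(dat, seq_len(3000)))
  b0 <- apc_bootstrap(dat, const, B = 5, seed = 1)
  expect_true(all(b0$se == 0))
  expect_true(all(b0$ci_lo == b0$ci_hi))
})

test_that("bootstrap percentile intervals cover the generator truth", {
  w <- linear_world()
  dat <- apcmech:::apc_resample(w$data, seq_len(6000))
  boot <- apc_bootstrap(dat, function(d) estimate_pathtrace(d),
    B = 150, seed = 9
  )
  tru <- true_apc_effects(w$params, "pathtrace")
  nonref <- tru$category != 1
  covered <- tru$estimate[nonref] >= boot$ci_lo[nonref] &
    tru$estimate[nonref] <= boot$ci_hi[nonref]
  expect_gte(mean(covered), 0.85) # ~95% nominal, one dataset
  expect_equal(attr(boot, "B_effective"), 150L)
})

test_that("bootstrap aborts when too many replicates fail", {
  w <- linear_world()
  dat <- apcmech:::apc_resample(w$data, seq_len(500))
  flaky <- local({
    calls <- 0L
    function(d) {
      calls <<- calls + 1L
      if (calls %% 2L == 0L) stop("boom")
      estimate_pathtrace(d)
    }
  })
  expect_error(
    apc_bootstrap(dat, flaky, B = 20, seed = 1, max_fail = 0.1),
    "aborted"
  )
})
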