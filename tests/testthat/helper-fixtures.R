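# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

paper_scheme <- function() apc_scheme(c(40, 95), c(1990, 2015), 5)

# small linear-variant world: exact path-tracing algebra applies
linear_world <- function() {
  fixture("linear_world", {
    cfg <- scenario_config("simple", "linear", n = 20000, seed = 101)
    params <- calibrate(cfg)
    list(cfg = cfg, params = params, data = generate_apc_data(cfg, params))
  })
}

# small probit-variant world
probit_world <- function() {
  fixture("probit_world", {
    cfg <- scenario_config("simple", "probit", n = 20000, seed = 202)
    params <- calibrate(cfg)
    list(cfg = cfg, params = params, data = generate_apc_data(cfg, params))
  })
}

# hand-built fit objects on a toy scheme (2 age, 2 period, 3 cohort
# categories) for closed-form path-tracing checks
toy_fits <- function(gamma, delta, extra_mediator = NULL) {
  sch <- apc_scheme(c(0, 10), c(2000, 2010), 5)
  med <- list(structure(
    list(
      name = "m1", kind = "continuous", family = "linear",
      exposures = "period", scheme = sch, n = 100,
      coef = c(`(Intercept)` = 0, period2 = gamma), vcov = NULL,
      sigma = 1, converged = TRUE, separation = FALSE
    ),
    class = "mediator_fit"
  ))
  ocoef <- c(`(Intercept)` = 0, age2 = 0.3, cohort2 = 0.1, cohort3 = 0.2,
    m1 = delta)
  mediators <- "m1"
  if (!is.null(extra_mediator)) {
    med[[2]] <- structure(
      list(
        name = "m2", kind = "continuous", family = "linear",
        exposures = "period", scheme = sch, n = 100,
        coef = c(`(Intercept)` = 0, period2 = extra_mediator[1]), vcov = NULL,
        sigma = 1, converged = TRUE, separation = FALSE
      ),
      class = "mediator_fit"
    )
    ocoef["m2"] <- extra_mediator[2]
    mediators <- c("m1", "m2")
  }
  ofit <- structure(
    list(
      family = "linear", mediators = mediators,
      direct_dims = c("age", "cohort"), confounder = NULL,
      interactions = character(), scheme = sch, n = 100,
      coef = ocoef, vcov = NULL, sigma = 0.5, converged = TRUE,
      separation = FALSE
    ),
    class = "outcome_fit"
  )
  list(mediator_fits = med, outcome_fit = ofit)
}
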