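# Monte Carlo integration extension of the mechanism-based estimator: simulate
# mediators under period draws, simulate potential outcomes under independent
# age/period/cohort draws (breaking the linear identity), then fit an
# identifiable APC dummy regression to the simulated records. Valid for any
# parametric mediator/outcome families, including logistic links.

#' Configuration of the Monte Carlo integration
#'
#' The age, period and cohort values of the simulated records are always drawn
#' independently - that is what makes the refit identifiable - and always span
#' the full empirical category range of the fitted data. Only the number of
#' draws, the draw design and the seed are tunable.
#'
#' @param draws total number of simulated records (the factorial design rounds
#'   up to a whole number of replicates per category triple).
#' @param design `"factorial"` (every (age, period, cohort) category triple,
#'   balanced; lower Monte Carlo variance) or `"random"` (independent uniform
#'   category draws).
#' @param seed integer seed for the simulation draws.
#' @param blocks number of replicate blocks used to report Monte Carlo error
#'   (SD of block-wise estimates scaled to the full-draw estimate).
#' @param reuse_p reuse the period draws of the mediator-simulation step as
#'   the period values of the outcome-simulation step (default), or regenerate
#'   them; estimates agree within Monte Carlo error either way.
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(draws = 1e6, design = c("factorial", "random"),
                      seed = 1L, blocks = 4L, reuse_p = TRUE) {
  design <- match.arg(design)
  if (draws < 1) stop("draws must be positive", call. = FALSE)
  if (blocks < 1) stop("blocks must be >= 1", call. = FALSE)
  structure(
    list(
      draws = draws, design = design, seed = as.integer(seed),
      blocks = as.integer(blocks), reuse_p = isTRUE(reuse_p)
    ),
    class = "mc_config"
  )
}

# Independent category draws covering the full empirical range.
mc_draw_design <- function(scheme, mc) {
  na <- scheme$n_age
  np <- scheme$n_period
  nc <- scheme$n_cohort
  if (mc$design == "factorial") {
    cells <- expand.grid(
      a_idx = seq_len(na), p_idx = seq_len(np), c_idx = seq_len(nc),
      KEEP.OUT.ATTRS = FALSE
    )
    m <- max(1L, ceiling(mc$draws / nrow(cells)))
    df <- cells[rep(seq_len(nrow(cells)), m), , drop = FALSE]
    df$block <- rep(seq_len(m), each = nrow(cells)) %% mc$blocks + 1L
  } else {
    n <- ceiling(mc$draws)
    df <- with_local_seed(derive_seed(mc$seed, "mc-design"), data.frame(
      a_idx = sample.int(na, n, replace = TRUE),
      p_idx = sample.int(np, n, replace = TRUE),
      c_idx = sample.int(nc, n, replace = TRUE)
    ))
    df$block <- seq_len(n) %% mc$blocks + 1L
  }
  if (!mc$reuse_p) {
    df$p_idx <- with_local_seed(
      derive_seed(mc$seed, "mc-regen-p"),
      sample.int(np, nrow(df), replace = TRUE)
    )
  }
  rownames(df) <- NULL
  df
}

# Inverse link of a fitted family name, with linear-probability clamping.
fit_linkinv <- function(family_name) {
  switch(family_name,
    probit = stats::pnorm,
    logistic = stats::plogis,
    linear = function(x) pmin(pmax(x, 0), 1)
  )
}

#' Simulate mediator values under period draws
#'
#' Applies each first-step mediator model to the drawn category values:
#' continuous mediators get Gaussian noise with the fitted residual SD; binary
#' mediators are drawn Bernoulli with the link-inverted mean. Draws must lie
#' within the category range the models were fitted on.
#'
#' @param mediator_fits list from [fit_mediator_models()] (or generator-truth
#'   fits from [params_to_fits()]).
#' @param draws data.frame with `p_idx` (plus `a_idx`/`c_idx`/confounder
#'   columns when a mediator model uses them).
#' @param seed integer seed.
#' @return `draws` with one appended column per mediator.
#' @export
simulate_mediators <- function(mediator_fits, draws, seed = 1L) {
  for (f in mediator_fits) {
    sch <- f$scheme
    rng <- list(
      a_idx = sch$n_age, p_idx = sch$n_period, c_idx = sch$n_cohort
    )
    for (v in intersect(names(rng), names(draws))) {
      if (any(draws[[v]] < 1 | draws[[v]] > rng[[v]])) {
        stop(
          v, " draws fall outside the empirically observed category range 1..",
          rng[[v]],
          call. = FALSE
        )
      }
    }
    dims <- intersect(f$exposures, c("age", "period", "cohort"))
    extra <- setdiff(f$exposures, dims)
    X <- build_design(draws, dims,
      confounder = if (length(extra)) extra else NULL, scheme = sch
    )
    lp <- drop(cbind(1, X) %*% f$coef)
    draws[[f$name]] <- with_local_seed(
      derive_seed(seed, "mc-mediator", f$name),
      if (f$kind == "continuous") {
        lp + stats::rnorm(length(lp), 0, f$sigma)
      } else {
        stats::rbinom(length(lp), 1, fit_linkinv(f$family)(lp))
      }
    )
  }
  draws
}

#' Simulate potential outcomes on independent APC draws
#'
#' Applies the second-step outcome model to simulated records whose age,
#' period and cohort values were drawn independently; the period value enters
#' only through the simulated mediators. A draw design that satisfies the
#' real-world identity `c = p - a + n_age` on every record is rejected - such
#' a design would reproduce the collinearity the method exists to break.
#'
#' @param outcome_fit a [fit_outcome_model()] result (or generator truth).
#' @param draws data.frame from [simulate_mediators()].
#' @param seed integer seed.
#' @return an object of class `simulated_world`.
#' @export
simulate_outcomes <- function(outcome_fit, draws, seed = 1L) {
  sch <- outcome_fit$scheme
  if (sch$n_age > 1 && sch$n_period > 1 &&
    all(draws$c_idx == draws$p_idx - draws$a_idx + sch$n_age)) {
    stop(paste(
      "the draw design satisfies the APC identity on every record;",
      "age, period and cohort draws must be independent"
    ), call. = FALSE)
  }
  X <- build_design(draws, outcome_fit$direct_dims, outcome_fit$mediators,
    outcome_fit$confounder,
    scheme = sch,
    interactions = outcome_fit$interactions %||% character()
  )
  lp <- drop(cbind(1, X) %*% outcome_fit$coef)
  draws$y <- with_local_seed(
    derive_seed(seed, "mc-outcome"),
    if (outcome_fit$family == "linear") {
      lp + stats::rnorm(length(lp), 0, outcome_fit$sigma)
    } else {
      stats::rbinom(length(lp), 1, fit_linkinv(outcome_fit$family)(lp))
    }
  )
  structure(
    list(draws = draws, outcome_family = outcome_fit$family, scheme = sch),
    class = "simulated_world"
  )
}

#' @export
print.simulated_world <- function(x, ...) {
  cat(sprintf(
    "Simulated world: %d draws, %s outcome, %d/%d/%d categories\n",
    nrow(x$draws), x$outcome_family,
    x$scheme$n_age, x$scheme$n_period, x$scheme$n_cohort
  ))
  invisible(x)
}

# Aggregate simulated records to (a, p, c) cells and fit the identifiable APC
# dummy regression on the aggregated sufficient statistics (exactly the
# record-level likelihood, since covariates vary only between cells).
fit_apc_cells <- function(df, scheme, family_name) {
  key <- (df$a_idx - 1) * scheme$n_period * scheme$n_cohort +
    (df$p_idx - 1) * scheme$n_cohort + df$c_idx
  n_cell <- as.vector(rowsum(rep(1, nrow(df)), key))
  y_cell <- as.vector(rowsum(df$y, key)) / n_cell
  keys <- sort(unique(key))
  cells <- data.frame(
    a_idx = (keys - 1) %/% (scheme$n_period * scheme$n_cohort) + 1,
    p_idx = ((keys - 1) %/% scheme$n_cohort) %% scheme$n_period + 1,
    c_idx = (keys - 1) %% scheme$n_cohort + 1
  )
  X <- build_design(cells, c("age", "period", "cohort"), scheme = scheme)
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) {
    stop(paste(
      "rank-deficient APC design on the simulated draws - the identity was",
      "not broken (or a category is unobserved)"
    ), call. = FALSE)
  }
  if (family_name == "linear") {
    fit <- stats::lm.wfit(Xi, y_cell, w = n_cell)
    stats::setNames(fit$coefficients, colnames(Xi))
  } else {
    fam <- variant_links(family_name)$family
    fit <- suppressWarnings(
      stats::glm.fit(Xi, y_cell, weights = n_cell, family = fam)
    )
    stats::setNames(fit$coefficients, colnames(Xi))
  }
}

coefs_to_estimates <- function(coefs, scheme) {
  rows <- list()
  ncat <- c(
    age = scheme$n_age, period = scheme$n_period, cohort = scheme$n_cohort
  )
  for (d in names(ncat)) {
    est <- numeric(ncat[[d]])
    for (k in seq_len(ncat[[d]])[-1]) est[k] <- unname(coefs[paste0(d, k)])
    rows[[d]] <- data.frame(
      dimension = d, category = seq_len(ncat[[d]]), estimate = est
    )
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fit the identifiable APC model to a simulated world
#'
#' Regression of the simulated outcomes on age, period and cohort dummies;
#' identifiable because the draws break the linear identity (full rank is
#' asserted). The family mirrors the outcome type: linear for continuous,
#' probit/logistic for binary simulated outcomes. Monte Carlo error is
#' reported as the SD of block-wise estimates scaled to the full draw count.
#'
#' @param world a [simulate_outcomes()] result.
#' @return an `apc_estimates` data.frame with an `mc_se` column.
#' @export
fit_apc_on_simulated <- function(world) {
  stopifnot(inherits(world, "simulated_world"))
  sch <- world$scheme
  coefs <- fit_apc_cells(world$draws, sch, world$outcome_family)
  out <- coefs_to_estimates(coefs, sch)
  blocks <- unique(world$draws$block)
  if (!is.null(world$draws$block) && length(blocks) > 1) {
    bmat <- vapply(blocks, function(b) {
      sub <- world$draws[world$draws$block == b, , drop = FALSE]
      coefs_to_estimates(
        fit_apc_cells(sub, sch, world$outcome_family), sch
      )$estimate
    }, numeric(nrow(out)))
    # SD across block estimates, scaled down to the pooled-draw estimate
    out$mc_se <- apply(bmat, 1, stats::sd) / sqrt(length(blocks))
  } else {
    out$mc_se <- NA_real_
  }
  apc_estimates(out,
    estimator = "mcfrontdoor", variant = world$outcome_family
  )
}

# Steps 3-5 from fitted (or true) model components.
mc_from_fits <- function(mediator_fits, outcome_fit, mc = mc_config(),
                         genotype_prev = NULL) {
  sch <- outcome_fit$scheme
  draws <- mc_draw_design(sch, mc)
  conf <- outcome_fit$confounder
  needs_conf <- !is.null(conf) ||
    any(vapply(
      mediator_fits,
      function(f) length(setdiff(f$exposures, c("age", "period", "cohort"))) > 0,
      logical(1)
    ))
  if (needs_conf) {
    if (is.null(genotype_prev)) {
      stop("models include a confounder; supply its prevalence", call. = FALSE)
    }
    nm <- conf %||% setdiff(
      unlist(lapply(mediator_fits, `[[`, "exposures")),
      c("age", "period", "cohort")
    )[1]
    draws[[nm]] <- with_local_seed(
      derive_seed(mc$seed, "mc-confounder"),
      stats::rbinom(nrow(draws), 1, genotype_prev)
    )
  }
  draws <- simulate_mediators(mediator_fits, draws, seed = mc$seed)
  world <- simulate_outcomes(outcome_fit, draws, seed = mc$seed)
  fit_apc_on_simulated(world)
}

#' Monte Carlo front-door estimation of APC effects
#'
#' Orchestrates the six-step procedure: (1) fit mediator models, (2) fit the
#' outcome model, (3) simulate mediators under period draws, (4) simulate
#' potential outcomes under independent age/period/cohort draws, (5) fit the
#' now-identifiable APC dummy regression to the simulated records ((6),
#' bootstrap standard errors, is [bootstrap_mc()]). Unlike path tracing this
#' is valid for logistic links, product terms and any other parametric forms.
#' Deterministic given the seeds.
#'
#' @inheritParams estimate_pathtrace
#' @param mc an [mc_config()].
#' @return an `apc_estimates` data.frame with an `mc_se` column.
#' @export
estimate_mcfrontdoor <- function(dataset, mediators = NULL, exposures = NULL,
                                 confounder = NULL, mc = mc_config(),
                                 variant = NULL) {
  mediators <- mediators %||% attr(dataset, "mediators")
  if (!length(mediators)) {
    stop("no mediators supplied: nothing to integrate over", call. = FALSE)
  }
  mfits <- fit_mediator_models(dataset, mediators, exposures, variant)
  ofit <- fit_outcome_model(dataset, mediators,
    confounder = confounder,
    variant = variant
  )
  prev <- if (!is.null(confounder)) {
    mean(dataset[[confounder]])
  } else {
    conf_expo <- setdiff(
      unlist(lapply(mfits, `[[`, "exposures")), c("age", "period", "cohort")
    )
    if (length(conf_expo)) mean(dataset[[conf_expo[1]]]) else NULL
  }
  mc_from_fits(mfits, ofit, mc, genotype_prev = prev)
}

#' Bootstrap standard errors for the Monte Carlo front-door estimator
#'
#' Resamples records with replacement and repeats the full estimation
#' (model fits plus Monte Carlo integration) on every replicate. The Monte
#' Carlo draws use common random numbers across replicates, so the bootstrap
#' SE reflects sampling uncertainty; integration error is reported separately
#' as `mc_se` by the point estimate.
#'
#' @inheritParams estimate_mcfrontdoor
#' @inheritParams apc_bootstrap
#' @return an `apc_boot` object (see [apc_bootstrap()]).
#' @export
bootstrap_mc <- function(dataset, mediators = NULL, exposures = NULL,
                         confounder = NULL, mc = mc_config(), B = 100L,
                         seed = 1L, max_fail = 0.1) {
  apc_bootstrap(
    dataset,
    function(d) {
      estimate_mcfrontdoor(d, mediators, exposures, confounder, mc)
    },
    B = B, seed = seed, max_fail = max_fail
  )
}

#' Generator-truth model components
#'
#' Expresses the data-generating process of a calibrated scenario as exact
#' first-step and second-step model objects (the generator is itself a dummy-
#' parameterized parametric model, so this representation is exact). Used to
#' compute reference effect values for simulation studies and to cross-check
#' estimators against the truth.
#'
#' @param params a [calibrate()] result.
#' @return list with `mediator_fits` and `outcome_fit`.
#' @export
params_to_fits <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  sch <- params$scheme
  xa1 <- centered_idx(1, sch$n_age)
  xc1 <- centered_idx(1, sch$n_cohort)
  mfits <- list()
  for (m in names(params$mediators)) {
    sp <- params$mediators[[m]]
    expo <- "period"
    coef <- c(
      `(Intercept)` = (if (sp$kind == "continuous") sp$m0 else sp$lat0) +
        sp$g_p * sp$htil[1] + sp$g_a * xa1 + sp$g_c * xc1
    )
    for (k in seq_len(sch$n_period)[-1]) {
      coef[paste0("period", k)] <- sp$g_p * (sp$htil[k] - sp$htil[1])
    }
    if (sp$g_a != 0) {
      expo <- c(expo, "age")
      for (k in seq_len(sch$n_age)[-1]) {
        coef[paste0("age", k)] <- sp$g_a * (k - 1)
      }
    }
    if (sp$g_c != 0) {
      expo <- c(expo, "cohort")
      for (k in seq_len(sch$n_cohort)[-1]) {
        coef[paste0("cohort", k)] <- sp$g_c * (k - 1)
      }
    }
    if (sp$g_g != 0) {
      expo <- c(expo, "genotype")
      coef["genotype"] <- sp$g_g
    }
    mfits[[m]] <- structure(
      list(
        name = m, kind = sp$kind,
        family = if (sp$kind == "binary") params$variant else "linear",
        exposures = expo, scheme = sch, n = NA_integer_,
        coef = reorder_coef(coef, expo, sch, extra = m), vcov = NULL,
        sigma = if (sp$kind == "continuous") sp$sigma else NULL,
        converged = TRUE, separation = FALSE
      ),
      class = "mediator_fit"
    )
  }
  ocoef <- c(
    `(Intercept)` = params$delta0 + params$alpha_direct * xa1 +
      params$theta_direct * xc1
  )
  for (k in seq_len(sch$n_age)[-1]) {
    ocoef[paste0("age", k)] <- params$alpha_direct * (k - 1)
  }
  for (k in seq_len(sch$n_cohort)[-1]) {
    ocoef[paste0("cohort", k)] <- params$theta_direct * (k - 1)
  }
  for (m in names(params$mediators)) {
    ocoef[m] <- params$mediators[[m]]$delta
  }
  conf <- NULL
  if (params$delta_g != 0) {
    ocoef["genotype"] <- params$delta_g
    conf <- "genotype"
  }
  ofit <- structure(
    list(
      family = params$variant, mediators = names(params$mediators),
      direct_dims = c("age", "cohort"), confounder = conf, scheme = sch,
      n = NA_integer_, coef = ocoef, vcov = NULL,
      sigma = if (params$variant == "linear") params$sigma_y else NULL,
      converged = TRUE, separation = FALSE
    ),
    class = "outcome_fit"
  )
  list(mediator_fits = mfits, outcome_fit = ofit)
}

# order truth coefficients the same way build_design orders columns
reorder_coef <- function(coef, exposures, scheme, extra = NULL) {
  dims <- intersect(c("age", "period", "cohort"), exposures)
  ord <- "(Intercept)"
  for (d in dims) {
    n <- switch(d,
      age = scheme$n_age, period = scheme$n_period, cohort = scheme$n_cohort
    )
    ord <- c(ord, paste0(d, seq_len(n)[-1]))
  }
  ord <- c(ord, setdiff(names(coef), ord))
  coef[ord]
}

#' Reference APC effects of a calibrated generator
#'
#' The per-category effect values an estimator should recover under correct
#' specification: for `"pathtrace"`, the exact path-tracing functional of the
#' generating coefficients (closed form - for binary mediators the products
#' live on the mediator's latent link scale); for `"mcfrontdoor"`, the Monte
#' Carlo front-door functional evaluated at the generating coefficients with
#' a large draw count.
#'
#' @param params a [calibrate()] result.
#' @param estimator `"pathtrace"` or `"mcfrontdoor"`.
#' @param mc [mc_config()] for the `"mcfrontdoor"` functional.
#' @return an `apc_estimates` data.frame.
#' @export
true_apc_effects <- function(params, estimator = c("pathtrace", "mcfrontdoor"),
                             mc = mc_config(draws = 2e6, seed = 1L)) {
  estimator <- match.arg(estimator)
  tf <- params_to_fits(params)
  if (estimator == "pathtrace") {
    out <- path_trace(tf$mediator_fits, tf$outcome_fit)
    attr(out, "estimator") <- "truth-pathtrace"
    out
  } else {
    out <- mc_from_fits(tf$mediator_fits, tf$outcome_fit, mc,
      genotype_prev = params$genotype_prevalence
    )
    attr(out, "estimator") <- "truth-mcfrontdoor"
    out
  }
}
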