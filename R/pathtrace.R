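# The classical mechanism-based estimator: mediator regressions on period (and
# further APC parents), an outcome regression on age, cohort and the
# mediators, and path-tracing (product-of-coefficients) recovery of the
# mediated period effect.

# Design matrix (no intercept column) for APC dummies + extra columns.
# Works on any data.frame carrying a_idx/p_idx/c_idx (e.g. Monte Carlo draws)
# when `scheme` is given explicitly.
build_design <- function(dataset, dims = character(), mediators = character(),
                         confounder = NULL, scheme = attr(dataset, "scheme"),
                         interactions = character()) {
  blocks <- list()
  if ("age" %in% dims) {
    blocks$age <- make_dummies(dataset$a_idx, scheme$n_age, "age")
  }
  if ("period" %in% dims) {
    blocks$period <- make_dummies(dataset$p_idx, scheme$n_period, "period")
  }
  if ("cohort" %in% dims) {
    blocks$cohort <- make_dummies(dataset$c_idx, scheme$n_cohort, "cohort")
  }
  for (m in mediators) {
    blocks[[m]] <- matrix(dataset[[m]],
      ncol = 1, dimnames = list(NULL, m)
    )
  }
  if (!is.null(confounder)) {
    blocks[[confounder]] <- matrix(dataset[[confounder]],
      ncol = 1, dimnames = list(NULL, confounder)
    )
  }
  # product terms "variable:dimension", e.g. "bmi:age": the variable times
  # each non-reference dummy of the dimension
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[2] %in% c("age", "period", "cohort")) {
      stop("interactions must be of the form 'variable:dimension'",
        call. = FALSE
      )
    }
    v <- dataset[[parts[1]]]
    if (is.null(v)) stop("unknown interaction variable: ", parts[1], call. = FALSE)
    idx <- switch(parts[2],
      age = dataset$a_idx, period = dataset$p_idx, cohort = dataset$c_idx
    )
    n_lev <- switch(parts[2],
      age = scheme$n_age, period = scheme$n_period, cohort = scheme$n_cohort
    )
    dm <- make_dummies(idx, n_lev, parts[2]) * v
    colnames(dm) <- paste0(parts[1], ":", colnames(dm))
    blocks[[ia]] <- dm
  }
  do.call(cbind, blocks)
}

# Shared least-squares / IRLS core with rank and separation diagnostics.
fit_glm_core <- function(y, X, family_name) {
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) {
    stop(paste(
      "singular design matrix - the requested covariates are linearly",
      "dependent (e.g. age, period and cohort dummies together reproduce",
      "the APC identity)"
    ), call. = FALSE)
  }
  if (family_name == "linear") {
    fit <- stats::lm.fit(Xi, y)
    res <- fit$residuals
    df_res <- length(y) - ncol(Xi)
    sigma2 <- sum(res^2) / max(df_res, 1)
    R <- qr.R(fit$qr)
    vcov <- sigma2 * chol2inv(R)[order(fit$qr$pivot), order(fit$qr$pivot)]
    dimnames(vcov) <- list(colnames(Xi), colnames(Xi))
    list(
      coef = stats::setNames(fit$coefficients, colnames(Xi)),
      vcov = vcov, sigma = sqrt(sigma2), converged = TRUE, separation = FALSE
    )
  } else {
    fam <- variant_links(family_name)$family
    fit <- suppressWarnings(stats::glm.fit(Xi, y, family = fam))
    w <- fit$weights
    XtWX <- crossprod(Xi * sqrt(w))
    vcov <- solve(XtWX)
    dimnames(vcov) <- list(colnames(Xi), colnames(Xi))
    sep <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) &&
      max(abs(fit$coefficients)) > 15
    if (sep) {
      warning("possible perfect separation: fitted probabilities of 0/1 with ",
        "extreme coefficients",
        call. = FALSE
      )
    }
    list(
      coef = stats::setNames(fit$coefficients, colnames(Xi)),
      vcov = vcov, sigma = NULL, converged = fit$converged, separation = sep
    )
  }
}

#' Fit first-step mediator models
#'
#' One regression per mediator on the dummy-coded exposures listed for it
#' (period by default; age, cohort or the confounder can be added when the
#' mediator has further parents). Continuous mediators are fit by linear
#' regression; binary mediators by probit or logistic regression matching the
#' dataset's variant (linear-probability regression in the linear variant).
#'
#' @param dataset an [apc_dataset()].
#' @param mediators mediator names; default: all mediators of the dataset.
#' @param exposures named list of character vectors per mediator, each a
#'   subset of `c("age", "period", "cohort")` plus optionally the confounder
#'   name; default `"period"` for every mediator.
#' @param variant estimation family variant; defaults to the dataset's.
#' @return list of `mediator_fit` objects.
#' @export
fit_mediator_models <- function(dataset, mediators = NULL, exposures = NULL,
                                variant = NULL) {
  stopifnot(inherits(dataset, "apc_dataset"))
  mediators <- mediators %||% attr(dataset, "mediators")
  variant <- variant %||% attr(dataset, "variant")
  if (is.na(variant)) {
    stop(
      "the dataset carries no model-family variant; supply `variant` ",
      "(\"probit\", \"logistic\" or \"linear\")",
      call. = FALSE
    )
  }
  kinds <- attr(dataset, "mediator_kinds")
  conf <- attr(dataset, "confounder")
  miss <- setdiff(mediators, colnames(dataset))
  if (length(miss)) {
    stop("mediator(s) not in dataset: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  fits <- list()
  for (m in mediators) {
    expo <- exposures[[m]] %||% "period"
    dims <- intersect(expo, c("age", "period", "cohort"))
    extra <- setdiff(expo, dims)
    if (length(extra) && (is.null(conf) || !all(extra == conf))) {
      stop("unknown exposure(s) for ", m, ": ", paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
    X <- build_design(dataset, dims,
      confounder = if (length(extra)) conf else NULL
    )
    fam <- if (identical(kinds[[m]], "binary") && variant != "linear") {
      variant
    } else {
      "linear"
    }
    core <- fit_glm_core(dataset[[m]], X, fam)
    fits[[m]] <- structure(
      c(
        list(
          name = m, kind = kinds[[m]], family = fam, exposures = expo,
          scheme = attr(dataset, "scheme"), n = nrow(dataset)
        ),
        core
      ),
      class = "mediator_fit"
    )
  }
  fits
}

#' Fit the second-step outcome model
#'
#' Regression of the outcome on age and cohort dummies, the mediators, and
#' optionally the confounder. Period dummies are excluded whenever period's
#' pathways are mediated (including period alongside age and cohort would
#' reproduce the APC identity and a singular design).
#'
#' @inheritParams fit_mediator_models
#' @param direct_dims APC dimensions entered directly (default age + cohort).
#' @param confounder confounder column to adjust for, or `NULL`.
#' @param interactions character vector of product terms
#'   (`"variable:dimension"`, e.g. `"bmi:age"`); such models are supported by
#'   the Monte Carlo front-door estimator but refused by [path_trace()].
#' @return an `outcome_fit` object.
#' @export
fit_outcome_model <- function(dataset, mediators = NULL,
                              direct_dims = c("age", "cohort"),
                              confounder = NULL, variant = NULL,
                              interactions = character()) {
  stopifnot(inherits(dataset, "apc_dataset"))
  mediators <- mediators %||% attr(dataset, "mediators")
  variant <- variant %||% attr(dataset, "variant")
  if (is.na(variant)) {
    stop(
      "the dataset carries no model-family variant; supply `variant` ",
      "(\"probit\", \"logistic\" or \"linear\")",
      call. = FALSE
    )
  }
  miss <- setdiff(c(mediators, confounder), colnames(dataset))
  if (length(miss)) {
    stop("column(s) not in dataset: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  X <- build_design(dataset, direct_dims, mediators, confounder,
    interactions = interactions
  )
  fam <- if (variant == "linear" ||
    !all(dataset$outcome %in% c(0, 1))) {
    "linear"
  } else {
    variant
  }
  core <- fit_glm_core(dataset$outcome, X, fam)
  structure(
    c(
      list(
        family = fam, mediators = mediators, direct_dims = direct_dims,
        confounder = confounder, interactions = interactions,
        scheme = attr(dataset, "scheme"), n = nrow(dataset)
      ),
      core
    ),
    class = "outcome_fit"
  )
}

#' @export
print.mediator_fit <- function(x, ...) {
  cat(sprintf(
    "Mediator model '%s' (%s, %s family), n = %d\n",
    x$name, x$kind, x$family, x$n
  ))
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf(
    "Outcome model (%s family) on %s + %d mediator(s)%s, n = %d\n",
    x$family, paste(x$direct_dims, collapse = "+"), length(x$mediators),
    if (!is.null(x$confounder)) paste0(" + ", x$confounder) else "", x$n
  ))
  invisible(x)
}

# Tidy per-category estimate container shared by all estimators.
apc_estimates <- function(df, estimator, variant = NA_character_,
                          note = NULL) {
  structure(df,
    class = c("apc_estimates", "data.frame"),
    estimator = estimator, variant = variant, note = note, reference = 1L
  )
}

#' @export
print.apc_estimates <- function(x, ...) {
  cat(sprintf(
    "APC effect estimates (%s estimator%s)\n", attr(x, "estimator"),
    if (!is.na(attr(x, "variant"))) paste0(", ", attr(x, "variant")) else ""
  ))
  if (!is.null(attr(x, "note"))) cat("  note:", attr(x, "note"), "\n")
  for (d in unique(x$dimension)) {
    sub <- x[x$dimension == d, ]
    cat(sprintf(
      "  %-7s trend %+.4f per category (%d categories)\n",
      d, trend_slope(sub$category, sub$estimate), nrow(sub)
    ))
  }
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Linear trend of per-category effect estimates
#'
#' Ordinary least-squares slope of estimate on category index; the summary
#' used to compare estimated effect curves between model specifications (an
#' omitted pathway reattributes mostly the linear component of the period
#' effect through the APC identity).
#'
#' @param category integer category indices.
#' @param estimate effect estimates.
#' @return the slope (effect change per category).
#' @export
trend_slope <- function(category, estimate) {
  stats::cov(category, estimate) / stats::var(category)
}

#' Path-tracing recovery of the APC effects
#'
#' Age and cohort effects are read from the outcome model; the mediated
#' period effect per period category is the sum over mediators of the product
#' of the mediator model's period-category coefficient and the mediator's
#' outcome coefficient. When a mediator model includes age or cohort among
#' its exposures, the corresponding products are added to that dimension's
#' direct estimates. Valid for linear and probit fits without product terms;
#' probit products are exact on the latent-propensity scale and are flagged
#' as latent-scale approximations of probability effects. Logistic fits are
#' refused: the product rule does not hold under a logit link - use
#' [estimate_mcfrontdoor()].
#'
#' @param mediator_fits list from [fit_mediator_models()].
#' @param outcome_fit an [fit_outcome_model()] result.
#' @return an `apc_estimates` data.frame with columns `dimension`, `category`,
#'   `estimate` (reference category 1 has estimate 0).
#' @export
path_trace <- function(mediator_fits, outcome_fit) {
  stopifnot(inherits(outcome_fit, "outcome_fit"))
  fams <- c(
    outcome_fit$family,
    vapply(mediator_fits, `[[`, character(1), "family")
  )
  if (any(fams == "logistic")) {
    stop(paste(
      "path tracing is invalid for logistic-link fits (the product rule",
      "holds only for linear and probit models); use estimate_mcfrontdoor()"
    ), call. = FALSE)
  }
  all_coefs <- c(
    names(outcome_fit$coef),
    unlist(lapply(mediator_fits, function(f) names(f$coef)))
  )
  if (any(grepl(":", all_coefs, fixed = TRUE))) {
    stop(paste(
      "path tracing is invalid in models with product terms;",
      "use estimate_mcfrontdoor()"
    ), call. = FALSE)
  }
  scheme <- outcome_fit$scheme
  ncat <- c(
    age = scheme$n_age, period = scheme$n_period, cohort = scheme$n_cohort
  )
  for (f in mediator_fits) {
    if (!f$name %in% outcome_fit$mediators) {
      stop(
        "mediator '", f$name, "' has a first-step fit but is absent from ",
        "the outcome model",
        call. = FALSE
      )
    }
  }
  rows <- list()
  for (d in c("age", "period", "cohort")) {
    est <- numeric(ncat[[d]])
    ks <- seq_len(ncat[[d]])[-1] # non-reference categories
    if (d %in% outcome_fit$direct_dims) {
      for (k in ks) est[k] <- unname(outcome_fit$coef[paste0(d, k)])
    }
    for (f in mediator_fits) {
      if (d %in% f$exposures) {
        delta <- unname(outcome_fit$coef[f$name])
        for (k in ks) {
          est[k] <- est[k] + unname(f$coef[paste0(d, k)]) * delta
        }
      }
    }
    rows[[d]] <- data.frame(
      dimension = d, category = seq_len(ncat[[d]]), estimate = est
    )
  }
  binary_med <- any(vapply(
    mediator_fits, function(f) f$kind == "binary" && f$family == "probit",
    logical(1)
  ))
  apc_estimates(
    do.call(rbind, c(rows, make.row.names = FALSE)),
    estimator = "pathtrace",
    variant = outcome_fit$family,
    note = if (binary_med) {
      "probit products are latent-scale approximations for binary mediators"
    }
  )
}

#' Delta-method standard error of a coefficient product
#'
#' First-order Taylor standard error of `gamma * delta`,
#' `sqrt(gamma^2 se_delta^2 + delta^2 se_gamma^2)`; appropriate for a single
#' linear pathway. Multi-pathway or non-linear settings need the bootstrap.
#'
#' @param gamma,delta coefficient estimates (vectorized).
#' @param gamma_se,delta_se their standard errors.
#' @return standard error(s) of the product.
#' @export
#' @examples
#' delta_method_se(0.5, 0.4, 0.1, 0.2)
delta_method_se <- function(gamma, delta, gamma_se, delta_se) {
  sqrt(gamma^2 * delta_se^2 + delta^2 * gamma_se^2)
}

#' Delta-method SEs for a single mediated pathway
#'
#' Per-period-category standard errors of the path product from one linear
#' mediator fit and a linear outcome fit. Refuses non-linear families or
#' multi-mediator outcome models (bootstrap those instead).
#'
#' @param mediator_fit a `mediator_fit` (linear family).
#' @param outcome_fit an `outcome_fit` (linear family) whose only mediator is
#'   the one fitted.
#' @return data.frame with `category`, `estimate`, `se`.
#' @export
delta_method_se_path <- function(mediator_fit, outcome_fit) {
  if (mediator_fit$family != "linear" || outcome_fit$family != "linear") {
    stop("delta-method SEs are provided for linear models only; use the bootstrap",
      call. = FALSE
    )
  }
  if (length(outcome_fit$mediators) != 1L ||
    outcome_fit$mediators != mediator_fit$name) {
    stop("delta-method SEs cover a single pathway; use the bootstrap",
      call. = FALSE
    )
  }
  np <- mediator_fit$scheme$n_period
  m <- mediator_fit$name
  delta <- unname(outcome_fit$coef[m])
  delta_se <- sqrt(outcome_fit$vcov[m, m])
  out <- data.frame(category = seq_len(np), estimate = 0, se = 0)
  for (k in seq_len(np)[-1]) {
    nm <- paste0("period", k)
    g <- unname(mediator_fit$coef[nm])
    g_se <- sqrt(mediator_fit$vcov[nm, nm])
    out$estimate[k] <- g * delta
    out$se[k] <- delta_method_se(g, delta, g_se, delta_se)
  }
  out
}

#' One-call path-tracing estimation
#'
#' Fits the mediator and outcome models and applies [path_trace()].
#'
#' @inheritParams fit_mediator_models
#' @inheritParams fit_outcome_model
#' @return an `apc_estimates` data.frame.
#' @export
estimate_pathtrace <- function(dataset, mediators = NULL, exposures = NULL,
                               confounder = NULL, variant = NULL) {
  mediators <- mediators %||% attr(dataset, "mediators")
  mfits <- fit_mediator_models(dataset, mediators, exposures, variant)
  ofit <- fit_outcome_model(dataset, mediators,
    confounder = confounder,
    variant = variant
  )
  path_trace(mfits, ofit)
}
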