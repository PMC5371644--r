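# Record-level simulation of the synthetic cardiovascular-mortality study.

# Draw mediator values for records with category indices (and genotype) in
# place. Used by the generator and by the calibration intercept tuner.
draw_mediators <- function(params, df) {
  lk <- variant_links(params$variant)
  n <- nrow(df)
  for (m in names(params$mediators)) {
    sp <- params$mediators[[m]]
    lat <- mediator_latent(params, m, df)
    df[[m]] <- if (sp$kind == "continuous") {
      lat + stats::rnorm(n, 0, sp$sigma)
    } else {
      pr <- lk$linkinv(lat)
      if (params$variant == "linear") pr <- pmin(pmax(pr, 0), 1)
      stats::rbinom(n, 1, pr)
    }
  }
  df
}

#' Generate a synthetic APC dataset
#'
#' Draws `config$n` individuals with age ~ Uniform over the age range and
#' period ~ Uniform over the calendar range (cohort = period - age),
#' categorizes them under the scheme, draws the four period mediators from
#' their parent-indexed models, and draws the cardiovascular-death outcome
#' from age and cohort category effects, the mediators, and (in the
#' confounding scenario) the genotype. Binary variables use the variant's
#' link; the linear variant produces a continuous outcome with Gaussian noise.
#' Fully reproducible given `config$seed`.
#'
#' @param config a [scenario_config()].
#' @param params optional pre-computed [calibrate()] output for `config`.
#' @return an [apc_dataset()] with the generating `params` attached to its
#'   provenance.
#' @export
#' @examples
#' dat <- generate_apc_data(scenario_config("simple", "probit", n = 500))
#' nrow(dat)
generate_apc_data <- function(config, params = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(params)) params <- calibrate(config)
  stopifnot(inherits(params, "generator_params"))
  lk <- variant_links(config$variant)
  sch <- params$scheme
  n <- config$n
  df <- with_local_seed(derive_seed(config$seed, "generate"), {
    age <- stats::runif(n, min(sch$age_edges), max(sch$age_edges))
    period <- stats::runif(n, min(sch$period_edges), max(sch$period_edges))
    df <- data.frame(age = age, period = period, cohort = period - age)
    df <- cbind(df, apc_categorize(age, period, sch))
    if (config$scenario == "confounding") {
      df$genotype <- stats::rbinom(n, 1, config$genotype_prevalence)
    }
    df <- draw_mediators(params, df)
    lp <- latent_outcome(params, df)
    df$outcome <- if (config$variant == "linear") {
      lp + stats::rnorm(n, 0, params$sigma_y)
    } else {
      stats::rbinom(n, 1, lk$linkinv(lp))
    }
    df
  })
  apc_dataset(
    df,
    scheme = sch,
    mediators = names(params$mediators),
    mediator_kinds = vapply(params$mediators, `[[`, character(1), "kind"),
    confounder = if (config$scenario == "confounding") "genotype" else NULL,
    variant = config$variant,
    provenance = list(config = config, params = params)
  )
}

#' Variance-based attribution of the latent linear predictor
#'
#' Recomputes, on a generated dataset, the share of the total APC contribution
#' to the latent linear predictor attributable to age, to the period-mediated
#' pathways and to cohort, plus each mediator's share of the period-mediated
#' component. Components are the systematic parts of the latent predictor:
#' the age contribution (direct plus age-via-BMI), the summed
#' `delta_m * E[M_m | period]` period pathways, and the cohort contribution
#' (direct plus cohort-via-smoking); binary-mediator means hold other parents
#' at their population-average latent contribution. Shares are the component
#' variances normalized over the three APC components.
#'
#' @param params the [calibrate()] output that generated the data.
#' @param dataset the matching [generate_apc_data()] output.
#' @return a list with `shares` (length-3, sums to 1), `mediator_shares`
#'   (share of the period-mediated variance per mediator, covariance-free
#'   normalization), `age_via_bmi_share`, `cohort_via_smoking_share`,
#'   `genotype_diagnostic` (variance of the genotype contribution relative to
#'   the age and cohort components) and the raw component `variances`.
#' @export
attribution_shares <- function(params, dataset) {
  stopifnot(
    inherits(params, "generator_params"),
    inherits(dataset, "apc_dataset")
  )
  prov <- attr(dataset, "provenance")
  cfg <- prov$config
  if (is.null(cfg) || !identical(cfg$scenario, params$scenario) ||
    !identical(cfg$variant, params$variant) ||
    !identical(attr(dataset, "scheme")[c("age_edges", "period_edges")],
               params$scheme[c("age_edges", "period_edges")])) {
    stop("dataset was not generated under these generator parameters",
      call. = FALSE
    )
  }
  lk <- variant_links(params$variant)
  sch <- params$scheme
  xa <- centered_idx(dataset$a_idx, sch$n_age)
  xc <- centered_idx(dataset$c_idx, sch$n_cohort)
  prev <- params$genotype_prevalence

  # age component: direct + age-via-BMI
  bmi <- params$mediators$bmi
  age_direct <- params$alpha_direct * xa
  age_via_bmi <- bmi$delta * bmi$g_a * xa
  age_comp <- age_direct + age_via_bmi

  # period component: summed delta_m * E[M_m | period]
  med_parts <- sapply(names(params$mediators), function(m) {
    sp <- params$mediators[[m]]
    if (sp$kind == "continuous") {
      sp$delta * sp$g_p * sp$htil[dataset$p_idx]
    } else {
      mu <- lk$linkinv(sp$lat0 + sp$g_g * prev + sp$g_p * sp$htil)
      sp$delta * (mu[dataset$p_idx] - mean(mu))
    }
  })
  period_comp <- rowSums(med_parts)

  # cohort component: direct + cohort-via-smoking
  smo <- params$mediators$smoking
  coh_via_smoking <- smo$delta *
    (lk$linkinv(smo$lat0 + smo$g_g * prev + smo$g_c * xc) -
      lk$linkinv(smo$lat0 + smo$g_g * prev))
  coh_comp <- params$theta_direct * xc + coh_via_smoking

  v <- c(
    age = stats::var(age_comp), period = stats::var(period_comp),
    cohort = stats::var(coh_comp)
  )
  shares <- if (sum(v) > 0) v / sum(v) else c(age = NA, period = NA, cohort = NA)

  vm <- apply(med_parts, 2, stats::var)
  med_shares <- if (sum(vm) > 0) vm / sum(vm) else vm

  gd <- NULL
  if (params$scenario == "confounding" && !is.null(dataset$genotype)) {
    d_pi_g <- mean(lk$linkinv(smo$lat0 + smo$g_g + smo$g_p * smo$htil) -
      lk$linkinv(smo$lat0 + smo$g_p * smo$htil))
    g_tot <- params$delta_g + bmi$delta * bmi$g_g + smo$delta * d_pi_g
    vg <- stats::var(g_tot * dataset$genotype)
    gd <- list(
      variance = vg,
      vs_age = if (v[["age"]] > 0) vg / v[["age"]] else NA,
      vs_cohort = if (v[["cohort"]] > 0) vg / v[["cohort"]] else NA
    )
  }

  list(
    shares = shares,
    mediator_shares = med_shares,
    age_via_bmi_share = if (v[["age"]] > 0) {
      stats::var(age_via_bmi) / v[["age"]]
    } else {
      0
    },
    # routed smoking share on the link (path-product) scale; see calibrate()
    cohort_via_smoking_share = if (params$theta_direct != 0 || smo$g_c != 0) {
      lat_ind <- smo$delta * smo$g_c * xc
      lat_tot <- (params$theta_direct + smo$delta * smo$g_c) * xc
      if (stats::var(lat_tot) > 0) stats::var(lat_ind) / stats::var(lat_tot) else 0
    } else {
      0
    },
    genotype_diagnostic = gd,
    variances = v
  )
}
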