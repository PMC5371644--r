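# Scenario configuration for the synthetic cardiovascular-mortality generator.

#' Default mediator specifications
#'
#' The four period mediators of the cardiovascular-mortality world and their
#' sign structure: the direction of the period effect on each mediator and of
#' each mediator on CVD death. `unmeasured` (continuous, standardized) stands
#' for the pool of unmeasured period influences and responds linearly to the
#' period category; the three measured mediators respond through monotone
#' logistic-shaped curves of the period index. `unmeasured` and `bmi` are
#' continuous; `smoking` and `statin` are binary with variant-specific link
#' baselines (linear-probability parameters in the linear variant).
#'
#' @param variant `"probit"`, `"logistic"` or `"linear"`.
#' @return named list of mediator spec lists.
#' @export
default_mediator_specs <- function(variant = "probit") {
  assert_one_of(variant, c("probit", "logistic", "linear"), "variant")
  # g_p magnitudes: latent-scale swing of the period pathway per unit of the
  # standardized period transform; chosen once to give realistic trajectories
  # (smoking prevalence falling ~45% -> ~19%, statin uptake ~3% -> ~32% across
  # 1990-2015, BMI drifting up ~2.4 kg/m2, in the probit variant).
  gp <- switch(variant,
    probit = c(unmeasured = 0.40, bmi = 1.20, smoking = 0.40, statin = 0.55),
    logistic = c(unmeasured = 0.40, bmi = 1.20, smoking = 0.70, statin = 0.95),
    linear = c(unmeasured = 0.40, bmi = 1.20, smoking = 0.075, statin = 0.065)
  )
  # genotype -> binary-mediator effect, on the mediator's link scale
  gg_smoking <- switch(variant, probit = 0.30, logistic = 0.50, linear = 0.08)
  lk <- variant_links(variant)
  list(
    unmeasured = list(
      name = "unmeasured", kind = "continuous", form = "linear",
      sign_p = -1, sign_y = +1, m0 = 0, sigma = 1,
      g_p = -gp[["unmeasured"]], shape_scale = NA
    ),
    bmi = list(
      name = "bmi", kind = "continuous", form = "monotone-nonlinear",
      sign_p = +1, sign_y = +1, m0 = 26, sigma = 4,
      g_p = +gp[["bmi"]], shape_scale = 1.0, g_g = 1.5
    ),
    smoking = list(
      name = "smoking", kind = "binary", form = "monotone-nonlinear",
      sign_p = -1, sign_y = +1, lat0 = lk$linkfun(0.30),
      g_p = -gp[["smoking"]], shape_scale = 1.5, g_g = gg_smoking
    ),
    statin = list(
      name = "statin", kind = "binary", form = "monotone-nonlinear",
      sign_p = +1, sign_y = -1, lat0 = lk$linkfun(0.12),
      g_p = +gp[["statin"]], shape_scale = 0.8
    )
  )
}

#' Standardized period transform of a mediator
#'
#' Evaluates the mediator's (increasing) period shape at every period category
#' and standardizes it to mean zero / unit variance over the uniform category
#' distribution; the sign of the period pathway is carried by the mediator's
#' `g_p` coefficient. `unmeasured` uses the identity (linear) shape; the
#' measured mediators use logistic ramps of the period index with
#' mediator-specific steepness.
#'
#' @param spec one element of [default_mediator_specs()].
#' @param n_period number of period categories.
#' @return numeric vector of length `n_period`.
#' @export
period_transform <- function(spec, n_period) {
  p <- seq_len(n_period)
  centre <- (n_period + 1) / 2
  raw <- if (identical(spec$form, "linear")) {
    p
  } else {
    stats::plogis((p - centre) / spec$shape_scale)
  }
  mu <- mean(raw)
  sdev <- sqrt(mean((raw - mu)^2))
  if (sdev == 0) {
    return(rep(0, n_period)) # single-category degenerate scheme
  }
  (raw - mu) / sdev
}

#' Declare a data-generating world
#'
#' Describes one simulation scenario of the synthetic cardiovascular-mortality
#' study: ages 40-95 over calendar years 1990-2015 in five-year categories,
#' CVD death as the outcome, four period mediators, and (per scenario) extra
#' mediator causes or a genotype confounder. Age accounts for 70% of the APC
#' effect by default, the period mediators for 20%, and birth cohort for 10%;
#' within the period effect the unmeasured mediator carries 40% and each
#' measured mediator 20%.
#'
#' @param scenario `"simple"` (mediators caused by period only),
#'   `"more_causes"` (age additionally lowers BMI, cohort additionally raises
#'   smoking) or `"confounding"` (a genotype raises BMI, smoking and CVD
#'   mortality).
#' @param variant `"probit"`, `"logistic"` (links for binary variables and the
#'   outcome) or `"linear"` (continuous outcome, linear-probability binary
#'   mediators).
#' @param n number of individual records to generate.
#' @param seed RNG seed for [generate_apc_data()].
#' @param shares length-3 numeric `(age, period, cohort)` variance shares of
#'   the total APC contribution to the latent linear predictor; must sum to 1.
#' @param mediator_shares named length-4 numeric, each mediator's share of the
#'   period-mediated contribution; must sum to 1.
#' @param age_to_bmi_share fraction of the total age effect routed through BMI
#'   (used in `more_causes` only).
#' @param cohort_to_smoking_share fraction of the total cohort effect routed
#'   through smoking (`more_causes` only).
#' @param genotype_prevalence fraction of carriers (`confounding` only).
#' @param baseline_risk_targets length-2 numeric: target outcome probability
#'   (or mean, in the linear variant) in the first and last age category,
#'   mimicking high-income-country CVD mortality.
#' @param age_range,period_range,width passed to [apc_scheme()].
#' @return an object of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config("simple", "probit", n = 1000, seed = 1)
#' cfg
scenario_config <- function(scenario = c("simple", "more_causes", "confounding"),
                            variant = c("probit", "logistic", "linear"),
                            n = 100000L, seed = 1L,
                            shares = c(age = 0.70, period = 0.20, cohort = 0.10),
                            mediator_shares = c(
                              unmeasured = 0.40, bmi = 0.20,
                              smoking = 0.20, statin = 0.20
                            ),
                            age_to_bmi_share = 0.30,
                            cohort_to_smoking_share = 0.30,
                            genotype_prevalence = 0.50,
                            baseline_risk_targets = c(0.005, 0.20),
                            age_range = c(40, 95),
                            period_range = c(1990, 2015),
                            width = 5) {
  scenario <- match.arg(scenario)
  variant <- match.arg(variant)
  shares <- unname(shares)
  if (length(shares) != 3L || any(shares < 0) || any(shares > 1) ||
    abs(sum(shares) - 1) > 1e-8) {
    stop("shares must be three fractions in [0,1] summing to 1", call. = FALSE)
  }
  ms <- mediator_shares
  if (is.null(names(ms)) || !setequal(
    names(ms),
    c("unmeasured", "bmi", "smoking", "statin")
  )) {
    stop("mediator_shares must be named unmeasured/bmi/smoking/statin",
      call. = FALSE
    )
  }
  if (any(ms < 0) || abs(sum(ms) - 1) > 1e-8) {
    stop("mediator_shares must be fractions in [0,1] summing to 1",
      call. = FALSE
    )
  }
  for (fr in c(age_to_bmi_share, cohort_to_smoking_share, genotype_prevalence)) {
    if (!is.numeric(fr) || fr < 0 || fr > 1) {
      stop("fractions must lie in [0,1]", call. = FALSE)
    }
  }
  if (length(baseline_risk_targets) != 2L ||
    any(baseline_risk_targets <= 0) ||
    (variant != "linear" && any(baseline_risk_targets >= 1)) ||
    diff(baseline_risk_targets) <= 0) {
    stop("baseline_risk_targets must be increasing probabilities", call. = FALSE)
  }
  if (n < 1) stop("n must be positive", call. = FALSE)
  structure(
    list(
      scenario = scenario, variant = variant, n = as.integer(n),
      seed = as.integer(seed), shares = c(
        age = shares[1], period = shares[2], cohort = shares[3]
      ),
      mediator_shares = ms[c("unmeasured", "bmi", "smoking", "statin")],
      age_to_bmi_share = age_to_bmi_share,
      cohort_to_smoking_share = cohort_to_smoking_share,
      genotype_prevalence = genotype_prevalence,
      baseline_risk_targets = baseline_risk_targets,
      scheme = apc_scheme(age_range, period_range, width)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s' (%s variant): n = %d, seed = %d\n",
    x$scenario, x$variant, x$n, x$seed
  ))
  cat(sprintf(
    "  APC shares age/period/cohort = %.2f/%.2f/%.2f\n",
    x$shares[1], x$shares[2], x$shares[3]
  ))
  cat(
    "  mediator shares:",
    paste(sprintf("%s %.2f", names(x$mediator_shares), x$mediator_shares),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' Read or write a scenario configuration as key-value text
#'
#' A flat `key: value` text format (one key per line, vectors space-separated)
#' so generator worlds can be described in files and passed to the CLI.
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  sch <- config$scheme
  lines <- c(
    paste("scenario:", config$scenario),
    paste("variant:", config$variant),
    paste("n:", config$n),
    paste("seed:", config$seed),
    paste("shares:", paste(config$shares, collapse = " ")),
    paste("mediator_shares:", paste(config$mediator_shares, collapse = " ")),
    paste("age_to_bmi_share:", config$age_to_bmi_share),
    paste("cohort_to_smoking_share:", config$cohort_to_smoking_share),
    paste("genotype_prevalence:", config$genotype_prevalence),
    paste("baseline_risk_targets:", paste(config$baseline_risk_targets,
      collapse = " "
    )),
    paste("age_range:", paste(range(sch$age_edges), collapse = " ")),
    paste("period_range:", paste(range(sch$period_edges), collapse = " ")),
    paste("width:", sch$width)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":")
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- lapply(kv, function(x) strsplit(trimws(paste(x[-1], collapse = ":")), "\\s+")[[1]])
  names(vals) <- keys
  num <- function(k, default = NULL) {
    if (is.null(vals[[k]])) default else as.numeric(vals[[k]])
  }
  scenario_config(
    scenario = vals[["scenario"]][1], variant = vals[["variant"]][1],
    n = num("n", 100000), seed = num("seed", 1),
    shares = num("shares", c(0.7, 0.2, 0.1)),
    mediator_shares = stats::setNames(
      num("mediator_shares", c(0.4, 0.2, 0.2, 0.2)),
      c("unmeasured", "bmi", "smoking", "statin")
    ),
    age_to_bmi_share = num("age_to_bmi_share", 0.30),
    cohort_to_smoking_share = num("cohort_to_smoking_share", 0.30),
    genotype_prevalence = num("genotype_prevalence", 0.50),
    baseline_risk_targets = num("baseline_risk_targets", c(0.005, 0.20)),
    age_range = num("age_range", c(40, 95)),
    period_range = num("period_range", c(1990, 2015)),
    width = num("width", 5)
  )
}
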