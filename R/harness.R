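# Experiment harness: scenario x variant x model-specification grids with
# replications, reproducing the simulation studies (mediator-removal
# sequences, omitted mediator parents, omitted confounding) at configurable
# scale, plus the effect-size sweeps.

#' Model-specification cells of a scenario
#'
#' Named estimation specifications: `correct` fits every pathway and adjusts
#' for the confounder as generated; the `drop_*` sequence removes the
#' unmeasured mediator, then BMI, then smoking, and `age_cohort_only` removes
#' all period mediators; `omit_extra_paths` (more_causes) drops age and cohort
#' from the mediator models; `omit_confounder` (confounding) drops the
#' genotype from all models.
#'
#' @param scenario scenario name.
#' @param cells optional subset of cell names.
#' @return named list of cell specifications (mediators, exposures,
#'   confounder).
#' @export
scenario_cells <- function(scenario, cells = NULL) {
  all_m <- c("unmeasured", "bmi", "smoking", "statin")
  expo_correct <- switch(scenario,
    simple = NULL,
    more_causes = list(bmi = c("period", "age"), smoking = c("period", "cohort")),
    confounding = list(
      bmi = c("period", "genotype"), smoking = c("period", "genotype")
    )
  )
  conf_correct <- if (scenario == "confounding") "genotype" else NULL
  keep_expo <- function(meds) expo_correct[intersect(names(expo_correct), meds)]
  removal <- list(
    drop_unmeasured = setdiff(all_m, "unmeasured"),
    drop_unmeasured_bmi = setdiff(all_m, c("unmeasured", "bmi")),
    drop_unmeasured_bmi_smoking = "statin",
    age_cohort_only = character()
  )
  out <- list(correct = list(
    mediators = all_m, exposures = expo_correct, confounder = conf_correct
  ))
  for (nm in names(removal)) {
    out[[nm]] <- list(
      mediators = removal[[nm]], exposures = keep_expo(removal[[nm]]),
      confounder = conf_correct
    )
  }
  if (scenario == "more_causes") {
    out$omit_extra_paths <- list(
      mediators = all_m, exposures = NULL, confounder = NULL
    )
  }
  if (scenario == "confounding") {
    out$omit_confounder <- list(
      mediators = all_m, exposures = NULL, confounder = NULL
    )
  }
  if (!is.null(cells)) {
    unknown <- setdiff(cells, names(out))
    if (length(unknown)) {
      stop("unknown cell(s) for scenario ", scenario, ": ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    out <- out[cells]
  }
  out
}

#' Declare a simulation experiment
#'
#' The desk-scale default (20 replications of n = 20,000) is sized so that
#' bias directions and orderings stabilize; the full-scale design of the
#' simulation study (1,000 replications of n = 100,000) is available by
#' setting `reps` and `n` explicitly.
#'
#' @param scenarios subset of `c("simple", "more_causes", "confounding")`.
#' @param variants subset of `c("probit", "logistic", "linear")`.
#' @param cells optional cell-name subset (see [scenario_cells()]).
#' @param reps replications per scenario x variant.
#' @param n records per replication.
#' @param estimator `"pathtrace"` or `"mcfrontdoor"` (required for logistic
#'   variants, where path tracing refuses).
#' @param seed master seed; every cell and replication derives its own.
#' @param mc [mc_config()] used when `estimator = "mcfrontdoor"`.
#' @param config_args further arguments passed to [scenario_config()]
#'   (e.g. non-default shares).
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(scenarios = c("simple", "more_causes", "confounding"),
                            variants = "probit", cells = NULL,
                            reps = 20L, n = 20000L,
                            estimator = c("pathtrace", "mcfrontdoor"),
                            seed = 1L, mc = mc_config(draws = 2e5),
                            config_args = list()) {
  estimator <- match.arg(estimator)
  scenarios <- match.arg(scenarios,
    c("simple", "more_causes", "confounding"),
    several.ok = TRUE
  )
  variants <- match.arg(variants, c("probit", "logistic", "linear"),
    several.ok = TRUE
  )
  if (estimator == "pathtrace" && "logistic" %in% variants) {
    stop("path tracing is invalid for the logistic variant; use mcfrontdoor",
      call. = FALSE
    )
  }
  structure(
    list(
      scenarios = scenarios, variants = variants, cells = cells,
      reps = as.integer(reps), n = as.integer(n), estimator = estimator,
      seed = as.integer(seed), mc = mc, config_args = config_args
    ),
    class = "experiment_spec"
  )
}

run_cell_estimator <- function(spec, dat, cell, cell_seed) {
  if (length(cell$mediators) == 0L) {
    # age-cohort model: no mediated pathways, period effect implicitly zero
    ofit <- fit_outcome_model(dat,
      mediators = character(),
      confounder = cell$confounder
    )
    return(path_trace(list(), ofit))
  }
  if (spec$estimator == "pathtrace") {
    estimate_pathtrace(dat, cell$mediators, cell$exposures, cell$confounder)
  } else {
    mc <- spec$mc
    mc$seed <- cell_seed
    estimate_mcfrontdoor(dat, cell$mediators, cell$exposures, cell$confounder,
      mc = mc
    )
  }
}

#' Run a simulation experiment
#'
#' For every scenario x variant, calibrates the generator once, then for each
#' replication generates a fresh dataset and runs the estimator under every
#' model-specification cell (cells share the replication's data, so biases
#' are paired comparisons). Replication failures are logged and counted; a
#' cell with more than `fail_threshold` failing replications is invalidated.
#' Deterministic given the spec's seed.
#'
#' @param spec an [experiment_spec()].
#' @param fail_threshold maximum tolerated fraction of failed replications.
#' @return an object of class `apc_experiment`: list with `results`
#'   (rep-level tidy estimates), `summary` (per-cell means, Monte Carlo SDs
#'   and paired biases vs the correctly-specified cell), `truth` (generator
#'   reference effects per scenario x variant), `failures`, and the `spec`.
#' @export
run_experiment <- function(spec, fail_threshold = 0.2) {
  stopifnot(inherits(spec, "experiment_spec"))
  results <- list()
  failures <- list()
  truths <- list()
  for (sc in spec$scenarios) {
    for (v in spec$variants) {
      cfg <- do.call(scenario_config, c(
        list(
          scenario = sc, variant = v, n = spec$n,
          seed = derive_seed(spec$seed, sc, v)
        ),
        spec$config_args
      ))
      params <- calibrate(cfg)
      if (spec$estimator == "pathtrace" && v != "logistic") {
        tru <- true_apc_effects(params, "pathtrace")
        truths[[paste(sc, v)]] <- data.frame(
          scenario = sc, variant = v, dimension = tru$dimension,
          category = tru$category, truth = tru$estimate
        )
      }
      cells <- scenario_cells(sc, spec$cells)
      for (r in seq_len(spec$reps)) {
        cfg_r <- cfg
        cfg_r$seed <- derive_seed(spec$seed, sc, v, "rep", r)
        dat <- generate_apc_data(cfg_r, params)
        for (cn in names(cells)) {
          est <- tryCatch(
            run_cell_estimator(
              spec, dat, cells[[cn]],
              derive_seed(spec$seed, sc, v, cn, r)
            ),
            error = function(e) conditionMessage(e)
          )
          if (is.character(est)) {
            failures[[length(failures) + 1]] <- data.frame(
              scenario = sc, variant = v, cell = cn, rep = r, message = est
            )
          } else {
            results[[length(results) + 1]] <- data.frame(
              scenario = sc, variant = v, cell = cn, rep = r,
              dimension = est$dimension, category = est$category,
              estimate = est$estimate
            )
          }
        }
      }
    }
  }
  results <- do.call(rbind, c(results, make.row.names = FALSE))
  failures <- if (length(failures)) {
    do.call(rbind, c(failures, make.row.names = FALSE))
  } else {
    data.frame(
      scenario = character(), variant = character(), cell = character(),
      rep = integer(), message = character()
    )
  }
  out <- structure(
    list(
      results = results, failures = failures,
      truth = if (length(truths)) {
        do.call(rbind, c(truths, make.row.names = FALSE))
      },
      spec = spec
    ),
    class = "apc_experiment"
  )
  out$summary <- summarize_experiment(out, fail_threshold)
  out
}

summarize_experiment <- function(x, fail_threshold = 0.2) {
  res <- x$results
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame())
  }
  key <- c("scenario", "variant", "cell", "dimension", "category")
  agg <- stats::aggregate(
    estimate ~ scenario + variant + cell + dimension + category,
    data = res, FUN = mean
  )
  names(agg)[names(agg) == "estimate"] <- "mean"
  sds <- stats::aggregate(
    estimate ~ scenario + variant + cell + dimension + category,
    data = res, FUN = stats::sd
  )
  nn <- stats::aggregate(
    estimate ~ scenario + variant + cell + dimension + category,
    data = res, FUN = length
  )
  agg$mc_sd <- sds$estimate
  agg$n_reps <- nn$estimate
  agg$mc_se <- agg$mc_sd / sqrt(agg$n_reps)
  # paired bias vs the correctly-specified cell, within replication
  correct <- res[res$cell == "correct", c(
    "scenario", "variant", "rep", "dimension", "category", "estimate"
  )]
  names(correct)[names(correct) == "estimate"] <- "est_correct"
  paired <- merge(res, correct,
    by = c("scenario", "variant", "rep", "dimension", "category")
  )
  paired$diff <- paired$estimate - paired$est_correct
  bias <- stats::aggregate(
    diff ~ scenario + variant + cell + dimension + category,
    data = paired, FUN = mean
  )
  names(bias)[names(bias) == "diff"] <- "bias"
  bias_se <- stats::aggregate(
    diff ~ scenario + variant + cell + dimension + category,
    data = paired, FUN = function(z) stats::sd(z) / sqrt(length(z))
  )
  names(bias_se)[names(bias_se) == "diff"] <- "bias_se"
  agg <- merge(agg, bias, by = key, all.x = TRUE)
  agg <- merge(agg, bias_se, by = key, all.x = TRUE)
  # invalidate cells with too many failures
  if (nrow(x$failures)) {
    fl <- stats::aggregate(rep ~ scenario + variant + cell,
      data = x$failures,
      FUN = length
    )
    names(fl)[names(fl) == "rep"] <- "n_failed"
    agg <- merge(agg, fl, by = c("scenario", "variant", "cell"), all.x = TRUE)
    agg$n_failed[is.na(agg$n_failed)] <- 0L
    agg$valid <- agg$n_failed <= fail_threshold * x$spec$reps
  } else {
    agg$n_failed <- 0L
    agg$valid <- TRUE
  }
  agg[order(agg$scenario, agg$variant, agg$cell, agg$dimension, agg$category), ]
}

#' Per-cell linear trends of the estimated effect curves
#'
#' Summarizes each replication's per-category estimates by their linear trend
#' ([trend_slope()]) and compares cells against the correctly-specified cell:
#' mean trend bias and its (paired, within-replication) standard error. Trend
#' biases are the natural summary of identity-driven bias, which reattributes
#' the linear component of an omitted pathway across dimensions.
#'
#' @param x an `apc_experiment`.
#' @return data.frame with one row per scenario x variant x cell x dimension.
#' @export
experiment_trends <- function(x) {
  stopifnot(inherits(x, "apc_experiment"))
  res <- x$results
  sp <- split(
    res,
    list(res$scenario, res$variant, res$cell, res$rep, res$dimension),
    drop = TRUE
  )
  tr <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      scenario = d$scenario[1], variant = d$variant[1], cell = d$cell[1],
      rep = d$rep[1], dimension = d$dimension[1],
      trend = trend_slope(d$category, d$estimate)
    )
  }))
  rownames(tr) <- NULL
  correct <- tr[tr$cell == "correct", c(
    "scenario", "variant", "rep", "dimension", "trend"
  )]
  names(correct)[names(correct) == "trend"] <- "trend_correct"
  paired <- merge(tr, correct, by = c("scenario", "variant", "rep", "dimension"))
  paired$diff <- paired$trend - paired$trend_correct
  out <- stats::aggregate(
    cbind(trend, trend_correct, diff) ~ scenario + variant + cell + dimension,
    data = paired, FUN = mean
  )
  names(out)[names(out) == "diff"] <- "trend_bias"
  se <- stats::aggregate(diff ~ scenario + variant + cell + dimension,
    data = paired, FUN = function(z) stats::sd(z) / sqrt(length(z))
  )
  names(se)[names(se) == "diff"] <- "trend_bias_se"
  merge(out, se, by = c("scenario", "variant", "cell", "dimension"))
}

#' @export
print.apc_experiment <- function(x, ...) {
  cat(sprintf(
    "APC simulation experiment: %s x %s, %d reps of n = %d (%s estimator)\n",
    paste(x$spec$scenarios, collapse = "/"),
    paste(x$spec$variants, collapse = "/"),
    x$spec$reps, x$spec$n, x$spec$estimator
  ))
  cat(sprintf(
    "  %d rep-level estimates, %d failures\n",
    nrow(x$results) %||% 0L, nrow(x$failures)
  ))
  invisible(x)
}

#' Report experiment or sweep results
#'
#' Prints human-readable per-cell tables (one per scenario x variant for
#' experiments; the per-increment bias table for sweeps). An empty result
#' prints an empty report.
#'
#' @param x an `apc_experiment` or `apc_sweep`.
#' @param digits significant digits.
#' @return `x`, invisibly.
#' @export
report <- function(x, digits = 4) UseMethod("report")

#' @export
report.apc_experiment <- function(x, digits = 4) {
  if (is.null(x$results) || nrow(x$results) == 0L) {
    cat("(empty experiment - nothing to report)\n")
    return(invisible(x))
  }
  tr <- experiment_trends(x)
  for (sc in unique(tr$scenario)) {
    for (v in unique(tr$variant[tr$scenario == sc])) {
      cat(sprintf("\n== scenario %s, %s variant ==\n", sc, v))
      sub <- tr[tr$scenario == sc & tr$variant == v, ]
      tab <- stats::reshape(
        sub[, c("cell", "dimension", "trend_bias")],
        idvar = "cell", timevar = "dimension", direction = "wide"
      )
      names(tab) <- sub("^trend_bias\\.", "trend bias: ", names(tab))
      print(format(tab, digits = digits), row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
report.apc_sweep <- function(x, digits = 4) {
  cat(sprintf(
    "Effect-size sweep (%s share varied, '%s' dropped):\n",
    attr(x, "sweep"), attr(x, "dropped")
  ))
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  skipped <- attr(x, "skipped")
  if (length(skipped)) {
    cat(
      "skipped infeasible increments:",
      paste(format(skipped), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Sweep the size of the period or cohort effect
#'
#' Reproduces the effect-size experiments: the period share is varied in
#' increments with the age share reduced correspondingly and the cohort share
#' held at its base value (set to zero at the 100% increment, where nothing
#' is left for it), or the cohort share is varied with the period share held
#' constant. At each increment, bias is generated by removing the unmeasured
#' mediator (by default) from the estimation model; the reported bias is the
#' paired trend difference against the correctly-specified model.
#'
#' @param scenario,variant generator scenario and variant.
#' @param sweep `"period"` or `"cohort"`.
#' @param increments swept shares in `[0, 1]`.
#' @param drop mediator(s) removed to generate bias.
#' @param reps,n replications and records per replication.
#' @param seed master seed.
#' @param base_cohort cohort share held constant in the period sweep.
#' @param base_period period share held constant in the cohort sweep.
#' @param estimator estimator name, as in [experiment_spec()].
#' @param mc [mc_config()] for the mcfrontdoor estimator.
#' @return an object of class `apc_sweep`: data.frame with one row per
#'   feasible increment x dimension (mean trend bias and its SE); infeasible
#'   share combinations are skipped and recorded in the `skipped` attribute.
#' @export
vary_effect_sizes <- function(scenario = "simple", variant = "probit",
                              sweep = c("period", "cohort"),
                              increments = seq(0, 1, by = 0.2),
                              drop = "unmeasured", reps = 10L, n = 20000L,
                              seed = 1L, base_cohort = 0.10, base_period = 0.20,
                              estimator = "pathtrace",
                              mc = mc_config(draws = 2e5)) {
  sweep <- match.arg(sweep)
  if (any(increments < 0 | increments > 1)) {
    stop("increments must lie in [0, 1]", call. = FALSE)
  }
  rows <- list()
  skipped <- numeric()
  for (s in increments) {
    shares <- if (sweep == "period") {
      coh <- if (s >= 1 - 1e-9) 0 else base_cohort
      c(age = 1 - s - coh, period = s, cohort = coh)
    } else {
      c(age = 1 - base_period - s, period = base_period, cohort = s)
    }
    if (shares[["age"]] < -1e-9) {
      skipped <- c(skipped, s)
      message(sprintf(
        "increment %.2f skipped: infeasible shares (age share would be %.2f)",
        s, shares[["age"]]
      ))
      next
    }
    shares[["age"]] <- max(shares[["age"]], 0)
    spec <- experiment_spec(
      scenarios = scenario, variants = variant,
      cells = c("correct", if (identical(sort(drop), sort(c(
        "unmeasured", "bmi", "smoking", "statin"
      )))) "age_cohort_only" else paste0("drop_", paste(drop, collapse = "_"))),
      reps = reps, n = n, estimator = estimator, mc = mc,
      seed = derive_seed(seed, "sweep", sweep, round(100 * s)),
      config_args = list(shares = unname(shares))
    )
    ex <- run_experiment(spec)
    tr <- experiment_trends(ex)
    tr <- tr[tr$cell != "correct", ]
    rows[[length(rows) + 1]] <- data.frame(
      sweep = sweep, share = s, dimension = tr$dimension,
      trend_correct = tr$trend_correct, trend_bias = tr$trend_bias,
      trend_bias_se = tr$trend_bias_se
    )
  }
  structure(
    do.call(rbind, c(rows, make.row.names = FALSE)),
    class = c("apc_sweep", "data.frame"),
    sweep = sweep, dropped = paste(drop, collapse = "+"), skipped = skipped
  )
}
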