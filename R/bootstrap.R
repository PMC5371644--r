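# Nonparametric bootstrap over individual records, wrapping any estimator
# that maps an apc_dataset to apc_estimates.

# Row-resample an apc_dataset, preserving its attributes.
apc_resample <- function(dataset, idx) {
  out <- as.data.frame(dataset)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(dataset)
  structure(out,
    class = attrs$class, scheme = attrs$scheme,
    mediators = attrs$mediators, mediator_kinds = attrs$mediator_kinds,
    confounder = attrs$confounder, variant = attrs$variant,
    provenance = attrs$provenance
  )
}

#' Nonparametric bootstrap standard errors and percentile intervals
#'
#' Resamples records with replacement at the original size, reruns the full
#' estimator on each replicate, and summarizes the replicate distribution:
#' the standard deviation across replicates estimates the standard error, and
#' the empirical 2.5%/97.5% quantiles give percentile 95% intervals.
#' Replicates in which the estimator fails are dropped and counted; more than
#' `max_fail` failing aborts.
#'
#' @param dataset an [apc_dataset()].
#' @param estimator function of one argument (a dataset) returning an
#'   `apc_estimates` data.frame, e.g.
#'   `function(d) estimate_pathtrace(d)`.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; replicate draws are derived deterministically.
#' @param max_fail maximum tolerated fraction of failing replicates.
#' @param level confidence level for the percentile intervals.
#' @return an object of class `apc_boot`: a data.frame with `dimension`,
#'   `category`, `estimate` (full-data point estimate), `se`, `ci_lo`,
#'   `ci_hi`, with attributes `B_effective` and `n_failed`.
#' @export
apc_bootstrap <- function(dataset, estimator, B = 500L, seed = 1L,
                          max_fail = 0.1, level = 0.95) {
  stopifnot(inherits(dataset, "apc_dataset"), B >= 2)
  point <- estimator(dataset)
  n <- nrow(dataset)
  reps <- matrix(NA_real_, nrow = nrow(point), ncol = B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- with_local_seed(
      derive_seed(seed, "bootstrap", b),
      sample.int(n, n, replace = TRUE)
    )
    est_b <- tryCatch(
      estimator(apc_resample(dataset, idx)),
      error = function(e) NULL
    )
    if (is.null(est_b) || nrow(est_b) != nrow(point)) {
      n_failed <- n_failed + 1L
      if (n_failed > max_fail * B) {
        stop(sprintf(
          "bootstrap aborted: %d of %d replicates failed (> %.0f%%)",
          n_failed, b, 100 * max_fail
        ), call. = FALSE)
      }
    } else {
      reps[, b] <- est_b$estimate
    }
  }
  ok <- !apply(is.na(reps), 2, all)
  reps <- reps[, ok, drop = FALSE]
  alpha <- (1 - level) / 2
  out <- data.frame(
    dimension = point$dimension, category = point$category,
    estimate = point$estimate,
    se = apply(reps, 1, stats::sd),
    ci_lo = apply(reps, 1, stats::quantile, probs = alpha, names = FALSE),
    ci_hi = apply(reps, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  )
  structure(out,
    class = c("apc_boot", "data.frame"),
    B_effective = sum(ok), n_failed = n_failed,
    estimator = attr(point, "estimator"), level = level
  )
}

#' @export
print.apc_boot <- function(x, ...) {
  cat(sprintf(
    "Bootstrap summary (%s estimator): %d effective replicates, %d failed\n",
    attr(x, "estimator"), attr(x, "B_effective"), attr(x, "n_failed")
  ))
  print(utils::head(as.data.frame(x), 8))
  invisible(x)
}
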