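# Internal helpers: seeded RNG isolation, seed derivation, link functions.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
#' afterwards, so package functions are reproducible without clobbering the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Deterministic integer hash used to give every scenario cell, replication and
#' bootstrap draw its own reproducible stream. Result is in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param ... further integers or strings identifying the sub-stream.
#' @return a single integer.
#' @export
#' @examples
#' derive_seed(1, "simple", 3L)
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(paste(p, collapse = "|"))) # stable, locale-free
    }
    for (v in as.double(p)) {
      # 32-bit-safe multiplicative mixing (Lehmer-style) in double precision
      h <- (h * 48271 + (v %% 2147483647) + 1) %% 2147483647
      h <- (h * 16807 + 12345) %% 2147483647
    }
  }
  as.integer(h %% 2147483646 + 1)
}

# Inverse link / density / quantile for the three generator variants.
# "linear" uses the identity link (linear-probability models for binary vars).
variant_links <- function(variant) {
  switch(variant,
    probit = list(
      linkinv = stats::pnorm, linkfun = stats::qnorm, dens = stats::dnorm,
      family = stats::binomial(link = "probit")
    ),
    logistic = list(
      linkinv = stats::plogis, linkfun = stats::qlogis, dens = stats::dlogis,
      family = stats::binomial(link = "logit")
    ),
    linear = list(
      linkinv = function(x) x, linkfun = function(p) p,
      dens = function(x) rep(1, length(x)),
      family = stats::gaussian()
    ),
    stop("unknown variant: ", variant, call. = FALSE)
  )
}

assert_one_of <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices) {
    stop(sprintf(
      "%s must be one of: %s (got '%s')", what,
      paste(choices, collapse = ", "), paste(x, collapse = ",")
    ), call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
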