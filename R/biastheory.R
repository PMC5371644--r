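# Closed-form expected coefficients of two-dimension APC models and of
# omitted-mediator estimation, in the scalar-slope (continuous A, P, C)
# parameterization. Because A = P - C exactly, substituting the identity into
# the linear associational model Y = eta + alpha*A + beta*P + theta*C + eps
# gives the expectation of every reduced model without any distributional
# assumptions.

#' Expected coefficients of a two-dimension APC model
#'
#' For true linear slopes `(alpha, beta, theta)` of age, period and cohort,
#' the expected coefficients of the model omitting one dimension follow from
#' substituting the identity `A = P - C`:
#' age-cohort model `(alpha + beta, theta + beta)` - the period effect is
#' attributed to age and cohort in equal parts; period-cohort model
#' `(beta + alpha, theta - alpha)`; age-period model
#' `(alpha - theta, beta + theta)`.
#'
#' @param alpha,beta,theta true age, period and cohort slopes.
#' @param model which two-dimension model is fitted.
#' @return list with `model`, `retained` (named expected coefficients) and
#'   `omitted` (the dimension whose effect is forced to zero).
#' @export
#' @examples
#' expected_coeffs(1.0, 0.5, 0.2, "age-cohort") # age 1.5, cohort 0.7
expected_coeffs <- function(alpha, beta, theta,
                            model = c("age-cohort", "period-cohort", "age-period")) {
  model <- match.arg(model)
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(theta))
  retained <- switch(model,
    "age-cohort" = c(age = alpha + beta, cohort = theta + beta),
    "period-cohort" = c(period = beta + alpha, cohort = theta - alpha),
    "age-period" = c(age = alpha - theta, period = beta + theta)
  )
  omitted <- setdiff(c("age", "period", "cohort"), names(retained))
  list(model = model, retained = retained, omitted = omitted)
}

#' Additive bias from omitting period mediators
#'
#' In the linear setting, omitting a period mediator from the outcome model
#' leaves its pathway unblocked; through the APC identity the omitted period
#' contribution is reattributed, adding the pathway product
#' `gamma (period to mediator) * delta (mediator to outcome)` to both the age
#' and the cohort slope, while the recovered (mediated) period slope loses the
#' same amount. Opposite-signed omitted pathways cancel.
#'
#' @param path_coeffs data.frame with columns `mediator`, `gamma`, `delta`
#'   (one row per mediator pathway).
#' @param omitted character vector of omitted mediator names (may be empty).
#' @return list with `age`, `cohort` and `period` additive biases.
#' @export
#' @examples
#' paths <- data.frame(mediator = "m2", gamma = -0.3, delta = 0.5)
#' omitted_mediator_bias(paths, "m2") # age/cohort -0.15, period +0.15
omitted_mediator_bias <- function(path_coeffs, omitted = character()) {
  stopifnot(
    is.data.frame(path_coeffs),
    all(c("mediator", "gamma", "delta") %in% names(path_coeffs))
  )
  unknown <- setdiff(omitted, path_coeffs$mediator)
  if (length(unknown)) {
    stop("omitted mediator(s) without path coefficients: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  sub <- path_coeffs[path_coeffs$mediator %in% omitted, , drop = FALSE]
  b <- sum(sub$gamma * sub$delta)
  list(age = b, cohort = b, period = -b)
}

#' Verify the closed forms against OLS on identity-constrained data
#'
#' Simulates linear data in which age and period are independent uniforms and
#' cohort is `period - age` (so the identity holds exactly), fits the three
#' two-dimension regressions, and compares the fitted coefficients with the
#' [expected_coeffs()] predictions: each must lie within `k` standard errors
#' (exact equality when `noise_sd = 0`).
#'
#' @param alpha,beta,theta true slopes of the associational model.
#' @param n sample size (>= 100).
#' @param noise_sd residual SD of the outcome.
#' @param seed RNG seed.
#' @param k allowed number of standard errors.
#' @return list with `pass` and a `comparison` data.frame (model, dimension,
#'   expected, fitted, se, z).
#' @export
verify_against_ols <- function(alpha, beta, theta, n = 10000, noise_sd = 1,
                               seed = 1L, k = 3) {
  if (n < 100) stop("n must be at least 100", call. = FALSE)
  dat <- with_local_seed(derive_seed(seed, "biastheory"), {
    A <- stats::runif(n, 40, 95)
    P <- stats::runif(n, 1990, 2015)
    C <- P - A
    Y <- 1 + alpha * A + beta * P + theta * C + stats::rnorm(n, 0, noise_sd)
    data.frame(A = A, P = P, C = C, Y = Y)
  })
  forms <- list(
    "age-cohort" = Y ~ A + C,
    "period-cohort" = Y ~ P + C,
    "age-period" = Y ~ A + P
  )
  dim_of <- c(A = "age", P = "period", C = "cohort")
  rows <- list()
  for (mod in names(forms)) {
    fit <- stats::lm(forms[[mod]], data = dat)
    expd <- expected_coeffs(alpha, beta, theta, mod)$retained
    # noiseless inputs fit perfectly; the SE-based z is handled below
    sm <- suppressWarnings(summary(fit))$coefficients
    for (v in rownames(sm)[-1]) {
      d <- dim_of[[v]]
      se <- sm[v, "Std. Error"]
      z <- if (se > 0) (sm[v, "Estimate"] - expd[[d]]) / se else
        ifelse(abs(sm[v, "Estimate"] - expd[[d]]) < 1e-8, 0, Inf)
      rows[[length(rows) + 1]] <- data.frame(
        model = mod, dimension = d, expected = expd[[d]],
        fitted = sm[v, "Estimate"], se = se, z = z
      )
    }
  }
  comparison <- do.call(rbind, rows)
  list(pass = all(abs(comparison$z) <= k), comparison = comparison)
}
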