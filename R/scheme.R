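# Time categorization: equal-width age/period bins and the derived overlapping
# cohort categories that preserve the linear identity C = P - A.

#' Build an age-period category scheme
#'
#' Partitions an age range and a calendar-period range into equal-width bins
#' and derives the overlapping cohort categories. Bins are half-open
#' `[lo, hi)`, except the final bin of each dimension, which is closed so the
#' range maximum belongs to the last category. Cohort categories are defined
#' on the category indices, `c_idx = p_idx - a_idx + n_age` (1-based), which
#' forces `n_cohort = n_age + n_period - 1` overlapping cohort groups and
#' preserves the linear identity among the categorized variables.
#'
#' @param age_range numeric length-2, `c(min, max)` age in years.
#' @param period_range numeric length-2, `c(min, max)` calendar year.
#' @param width bin width in years (default 5).
#' @return an object of class `apc_scheme`: a list with `age_edges`,
#'   `period_edges`, `n_age`, `n_period`, `n_cohort`, `width`.
#' @export
#' @examples
#' sch <- apc_scheme(c(40, 95), c(1990, 2015), 5)
#' sch$n_age     # 11
#' sch$n_cohort  # 15
apc_scheme <- function(age_range, period_range, width = 5) {
  check_range <- function(r, what) {
    if (length(r) != 2L || !is.numeric(r) || anyNA(r)) {
      stop(what, " must be a numeric vector c(min, max)", call. = FALSE)
    }
    if (r[2] <= r[1]) {
      stop(what, " is inverted or empty: max must exceed min", call. = FALSE)
    }
  }
  check_range(age_range, "age_range")
  check_range(period_range, "period_range")
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("width must be a single positive number", call. = FALSE)
  }
  edges <- function(r) {
    e <- seq(r[1], r[2], by = width)
    if (e[length(e)] < r[2]) e <- c(e, r[2]) # last bin extended to the maximum
    if (length(e) == 1L) e <- c(e, r[2])
    e
  }
  ae <- edges(age_range)
  pe <- edges(period_range)
  out <- structure(
    list(
      age_edges = ae, period_edges = pe,
      n_age = length(ae) - 1L, n_period = length(pe) - 1L,
      n_cohort = (length(ae) - 1L) + (length(pe) - 1L) - 1L,
      width = width
    ),
    class = "apc_scheme"
  )
  out
}

#' @export
print.apc_scheme <- function(x, ...) {
  cat(sprintf(
    "APC category scheme: %d age x %d period bins (width %g) -> %d overlapping cohorts\n",
    x$n_age, x$n_period, x$width, x$n_cohort
  ))
  cat(sprintf(
    "  ages [%g, %g], periods [%g, %g]; dummy variables %d/%d/%d\n",
    x$age_edges[1], x$age_edges[length(x$age_edges)],
    x$period_edges[1], x$period_edges[length(x$period_edges)],
    x$n_age - 1L, x$n_period - 1L, x$n_cohort - 1L
  ))
  invisible(x)
}

bin_index <- function(x, edges, what) {
  lo <- edges[1]
  hi <- edges[length(edges)]
  if (any(x < lo | x > hi, na.rm = TRUE) || anyNA(x)) {
    stop(sprintf("%s values outside scheme range [%g, %g]", what, lo, hi),
      call. = FALSE
    )
  }
  findInterval(x, edges, rightmost.closed = TRUE)
}

#' Categorize continuous age and period under a scheme
#'
#' Returns the 1-based age, period and derived cohort category indices. The
#' cohort index satisfies `c_idx = p_idx - a_idx + n_age`, so it ranges over
#' `1..n_cohort` with the earliest cohort (oldest age, earliest period) at 1.
#'
#' @param age,period numeric vectors of equal length.
#' @param scheme an [apc_scheme()].
#' @return a data.frame with integer columns `a_idx`, `p_idx`, `c_idx`.
#' @export
#' @examples
#' sch <- apc_scheme(c(40, 95), c(1990, 2015))
#' apc_categorize(c(40, 95, 62.3), c(1990, 1990, 2007.9), sch)
apc_categorize <- function(age, period, scheme) {
  stopifnot(inherits(scheme, "apc_scheme"))
  if (length(age) != length(period)) {
    stop("age and period must have the same length", call. = FALSE)
  }
  a <- bin_index(age, scheme$age_edges, "age")
  p <- bin_index(period, scheme$period_edges, "period")
  data.frame(a_idx = a, p_idx = p, c_idx = p - a + scheme$n_age)
}

# 0/1 indicator matrix for one categorical dimension, reference level omitted.
make_dummies <- function(idx, n_levels, prefix, reference = 1L) {
  if (length(reference) != 1L || reference < 1L || reference > n_levels) {
    stop(sprintf(
      "reference index for %s out of range 1..%d", prefix, n_levels
    ), call. = FALSE)
  }
  keep <- setdiff(seq_len(n_levels), reference)
  if (!length(keep)) { # single-category dimension: no indicator columns
    return(matrix(numeric(0), nrow = length(idx), ncol = 0))
  }
  m <- matrix(0,
    nrow = length(idx), ncol = length(keep),
    dimnames = list(NULL, paste0(prefix, keep))
  )
  for (j in seq_along(keep)) m[, j] <- as.numeric(idx == keep[j])
  m
}

#' Dummy-code the APC dimensions of a dataset
#'
#' One indicator column per non-reference category per requested dimension,
#' giving `sum(n_dim - 1)` columns in total (the identifiable dummy counts:
#' 10/4/14 for the default cardiovascular-mortality scheme).
#'
#' @param dataset an [apc_dataset()].
#' @param dimensions subset of `c("age", "period", "cohort")`.
#' @param reference named integer vector of reference category indices
#'   (default: first category of each dimension).
#' @return numeric matrix of indicators, columns named e.g. `age2 ... age11`.
#' @export
apc_dummy_encode <- function(dataset,
                             dimensions = c("age", "period", "cohort"),
                             reference = c(age = 1L, period = 1L, cohort = 1L)) {
  stopifnot(inherits(dataset, "apc_dataset"))
  dimensions <- match.arg(dimensions, c("age", "period", "cohort"),
    several.ok = TRUE
  )
  scheme <- attr(dataset, "scheme")
  ref <- c(age = 1L, period = 1L, cohort = 1L)
  ref[names(reference)] <- as.integer(reference)
  blocks <- list()
  if ("age" %in% dimensions) {
    blocks$age <- make_dummies(dataset$a_idx, scheme$n_age, "age", ref[["age"]])
  }
  if ("period" %in% dimensions) {
    blocks$period <- make_dummies(
      dataset$p_idx, scheme$n_period, "period", ref[["period"]]
    )
  }
  if ("cohort" %in% dimensions) {
    blocks$cohort <- make_dummies(
      dataset$c_idx, scheme$n_cohort, "cohort", ref[["cohort"]]
    )
  }
  do.call(cbind, blocks)
}
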