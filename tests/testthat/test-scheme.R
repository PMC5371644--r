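# Category scheme: bin construction, the overlapping-cohort identity, and
# dummy coding.

test_that("five-year categorization of the study ranges gives 11/5/15 categories", {
  sch <- apc_scheme(c(40, 95), c(1990, 2015), 5)
  expect_equal(sch$n_age, 11L)
  expect_equal(sch$n_period, 5L)
  expect_equal(sch$n_cohort, 15L)
  # identifiable dummy-variable counts: 10 age, 4 period, 14 cohort
  expect_equal(sch$n_age - 1L, 10L)
  expect_equal(sch$n_period - 1L, 4L)
  expect_equal(sch$n_cohort - 1L, 14L)
})

test_that("degenerate and short-range schemes follow n_cohort = n_age + n_period - 1", {
  one <- apc_scheme(c(0, 4), c(2000, 2004), 5)
  expect_equal(
    c(one$n_age, one$n_period, one$n_cohort), c(1L, 1L, 1L)
  )
  two <- apc_scheme(c(40, 49), c(1990, 1999), 5)
  expect_equal(
    c(two$n_age, two$n_period, two$n_cohort), c(2L, 2L, 3L)
  )
})

test_that("invalid ranges and widths are rejected", {
  expect_error(apc_scheme(c(95, 40), c(1990, 2015)), "inverted")
  expect_error(apc_scheme(c(40, 95), c(2015, 1990)), "inverted")
  expect_error(apc_scheme(c(40, 95), c(1990, 2015), width = 0), "positive")
  expect_error(apc_scheme(c(40, 95), c(1990, 2015), width = -5), "positive")
})

test_that("cohort count identity holds over randomized ranges and widths", {
  set.seed(42)
  for (i in 1:25) {
    lo_a <- runif(1, 0, 50)
    lo_p <- runif(1, 1900, 2000)
    w <- runif(1, 1, 10)
    sch <- apc_scheme(
      c(lo_a, lo_a + runif(1, 1, 60)),
      c(lo_p, lo_p + runif(1, 1, 40)), w
    )
    expect_equal(sch$n_cohort, sch$n_age + sch$n_period - 1L)
    expect_true(all(diff(sch$age_edges) > 0), info = "contiguous age bins")
    expect_true(all(diff(sch$period_edges) > 0))
  }
})

test_that("categorize returns bin indices consistent with the edges", {
  sch <- paper_scheme()
  # youngest age, earliest period -> cohort index n_age; oldest age, earliest
  # period -> the earliest cohort (last bin closed, so age 95 is category 11)
  idx <- apc_categorize(c(40, 95, 62.3), c(1990, 1990, 2007.9), sch)
  expect_equal(idx$a_idx, c(1L, 11L, 5L))
  expect_equal(idx$p_idx, c(1L, 1L, 4L))
  expect_equal(idx$c_idx, c(11L, 1L, 10L))
  expect_error(apc_categorize(39, 1990, sch), "outside")
  expect_error(apc_categorize(50, 2016, sch), "outside")
})

test_that("categorize inverts bin construction at every bin midpoint", {
  set.seed(7)
  for (i in 1:10) {
    sch <- apc_scheme(
      c(20, 20 + sample(10:60, 1)), c(1950, 1950 + sample(5:40, 1)),
      sample(2:8, 1)
    )
    a_mid <- (head(sch$age_edges, -1) + tail(sch$age_edges, -1)) / 2
    p_mid <- (head(sch$period_edges, -1) + tail(sch$period_edges, -1)) / 2
    expect_equal(
      apc_categorize(a_mid, rep(p_mid[1], length(a_mid)), sch)$a_idx,
      seq_len(sch$n_age)
    )
    expect_equal(
      apc_categorize(rep(a_mid[1], length(p_mid)), p_mid, sch)$p_idx,
      seq_len(sch$n_period)
    )
    # the cohort index identity, on every (midpoint, midpoint) pair
    grid <- expand.grid(a = a_mid, p = p_mid)
    idx <- apc_categorize(grid$a, grid$p, sch)
    expect_true(all(idx$c_idx == idx$p_idx - idx$a_idx + sch$n_age))
    expect_true(all(idx$c_idx >= 1 & idx$c_idx <= sch$n_cohort))
  }
})

test_that("dummy coding produces one indicator per non-reference category", {
  dat <- probit_world()$data
  X <- apc_dummy_encode(dat)
  expect_equal(ncol(X), 10L + 4L + 14L)
  expect_true(all(X %in% c(0, 1)))
  # per dimension, indicator rows sum to 1 unless the record sits in the
  # reference category (then 0)
  age_cols <- grep("^age", colnames(X))
  s <- rowSums(X[, age_cols, drop = FALSE])
  expect_true(all(s == as.numeric(dat$a_idx != 1L)))
  per_cols <- grep("^period", colnames(X))
  s <- rowSums(X[, per_cols, drop = FALSE])
  expect_true(all(s == as.numeric(dat$p_idx != 1L)))
  # reference-category records give an all-zero row
  ref <- dat$a_idx == 1 & dat$p_idx == 1 & dat$c_idx == 1
  if (any(ref)) {
    expect_true(all(X[ref, ] == 0))
  }
  # configurable reference
  X5 <- apc_dummy_encode(dat, "period", reference = c(period = 5L))
  expect_false("period5" %in% colnames(X5))
  expect_error(
    apc_dummy_encode(dat, "period", reference = c(period = 9L)),
    "out of range"
  )
})

test_that("a single-category dimension contributes zero dummy columns", {
  sch <- apc_scheme(c(40, 44), c(1990, 2015), 5)
  rec <- data.frame(age = c(41, 43), period = c(1991, 2011), outcome = c(0, 1))
  dat <- apc_dataset(rec, sch)
  X <- apc_dummy_encode(dat, "age")
  expect_equal(ncol(X), 0L)
})
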