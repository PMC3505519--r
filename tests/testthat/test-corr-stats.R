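test_that("pearson correlation matches its defining formula and handles degenerate input", {
  expect_equal(pearson_r(1:4, c(2, 4, 6, 8)), 1)
  expect_equal(pearson_r(1:4, c(-2, -4, -6, -8)), -1)

  # direct evaluation of the textbook formula for a small hand case
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- (length(x) - 1) * sd(x) * sd(y)
  expect_equal(pearson_r(x, y), num / den, tolerance = 1e-15)
  expect_equal(pearson_r(x, y), 0.8315218406202999, tolerance = 1e-12)
  expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-15)

  # moments container carries the pieces of the same formula
  m <- sample_moments(x, y)
  expect_equal(m$n, 4)
  expect_equal(m$cross_sum, num)
  expect_equal(m$var_x, var(x))
  expect_lte(abs(m$cross_sum), (m$n - 1) * sqrt(m$var_x * m$var_y) + 1e-12)

  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(c(2, 2, 2), 1:3), "zero variance")
  expect_error(pearson_r(c(1, NA, 3), 1:3), "[Mm]issing")
})

test_that("pearson correlation is invariant under positive affine maps and flips under negative slope", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    r <- pearson_r(x, y)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(x, -a * y + b), -r, tolerance = 1e-12)
  }
})

test_that("partial correlation reproduces the closed form and rejects invalid triples", {
  # published worked example, exact to formula precision
  rp <- partial_r(.51, -.78, -.66)
  expect_equal(rp, (.51 - .78 * .66) / sqrt((1 - .78^2) * (1 - .66^2)),
               tolerance = 1e-15)
  expect_equal(round(rp, 2), -0.01)
  expect_equal(rp, -0.01021001531, tolerance = 1e-7)

  # uncorrelated control changes nothing
  expect_equal(partial_r(0.37, 0, 0), 0.37)
  # hand-evaluated case
  expect_equal(partial_r(0.6, 0.5, 0.5), (0.6 - 0.25) / 0.75,
               tolerance = 1e-15)

  expect_error(partial_r(0.5, 1, 0.2), "control correlation")
  # triple that is not a valid correlation matrix
  expect_error(partial_r(0.9, 0.9, -0.9), "not positive semidefinite")
})

test_that("partial correlation from pairwise r agrees with the regression-residual definition", {
  set.seed(7)
  for (i in 1:10) {
    d <- generate(synthetic_spec(n = 60, corr = corr3(0.4, -0.5, 0.3),
                                 seed = 100 + i))
    x <- d[[1]]; y <- d[[2]]; z <- d[[3]]
    rp <- partial_r(pearson_r(x, y), pearson_r(x, z), pearson_r(y, z))
    expect_equal(rp, partial_r_residual_reference(x, y, z),
                 tolerance = 1e-12)
  }
})

test_that("t statistics follow the published closed forms", {
  # correlation test, unrounded published ratio
  expect_equal(round(t_from_r(-589 / 1629, 54), 2), -2.80)
  expect_equal(t_from_r(0, 17), 0)
  t_fb <- t_from_r(.48, 40)
  expect_equal(t_fb, .48 * sqrt(38 / (1 - .48^2)), tolerance = 1e-15)
  expect_lt(p_from_t(t_fb, 38), 0.01)  # a highly significant correlation

  # partial-correlation test
  rp <- partial_r(.51, -.78, -.66)
  expect_equal(round(t_from_partial_r(rp, 40), 2), -0.06)
  expect_equal(t_from_partial_r(0, 40), 0)
  expect_equal(t_from_partial_r(0.3, 20), 0.3 * sqrt(17 / (1 - 0.09)),
               tolerance = 1e-15)

  expect_warning(t_inf <- t_from_r(-1, 10), "infinite")
  expect_identical(t_inf, -Inf)
  expect_error(t_from_r(0.5, 2), "at least 3")
  expect_error(t_from_partial_r(0.5, 3), "at least 4")
})

test_that("t statistic is monotone in r and in n", {
  rs <- seq(-0.9, 0.9, by = 0.3)
  ts <- vapply(rs, t_from_r, numeric(1), n = 20)
  expect_true(all(diff(ts) > 0))
  ns <- c(5, 10, 40, 160)
  tn <- vapply(ns, function(n) abs(t_from_r(0.4, n)), numeric(1))
  expect_true(all(diff(tn) > 0))
})

test_that("two-sided p values match the t distribution and the published rounding", {
  expect_equal(round(p_from_t(t_from_r(-589 / 1629, 54), 52), 2), 0.01)
  rp <- partial_r(.51, -.78, -.66)
  expect_equal(round(p_from_t(t_from_partial_r(rp, 40), 37), 2), 0.95)
  expect_equal(p_from_t(0, 11), 1)
  # symmetry and complement of the central interval
  for (t in c(0.3, 1.7, 2.8)) {
    expect_equal(p_from_t(t, 9), p_from_t(-t, 9))
    central <- pt(t, 9) - pt(-t, 9)
    expect_equal(p_from_t(t, 9) + central, 1, tolerance = 1e-12)
  }
  expect_error(p_from_t(1, 0), "df")
})

test_that("coefficients of determination follow the nested-model identities", {
  expect_equal(r_squared(-.78), 0.6084)
  expect_equal(r_squared(0), 0)
  expect_equal(r_squared(ss_err = 8, ss_tot = 8), 0)
  expect_equal(r_squared(ss_err = 2, ss_tot = 8), 0.75)
  expect_error(r_squared(ss_err = -1, ss_tot = 2), "nonnegative")

  rp <- partial_r(.51, -.78, -.66)
  r1 <- r1_squared_from_partial(rp, -.78)
  expect_equal(round(r1, 7), 0.6084408)
  expect_equal(r1_squared_from_partial(0, -.78), 0.6084)
  expect_equal(r1_squared_from_partial(1, 0.3), 1)

  # R1^2 >= R0^2 for any valid correlation triple
  set.seed(3)
  k <- 0
  while (k < 25) {
    rs <- runif(3, -0.95, 0.95)
    rp <- tryCatch(partial_r(rs[1], rs[2], rs[3]), error = function(e) NULL)
    if (is.null(rp)) next
    k <- k + 1
    expect_gte(r1_squared_from_partial(rp, rs[2]), r_squared(rs[2]) - 1e-15)
  }
})
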