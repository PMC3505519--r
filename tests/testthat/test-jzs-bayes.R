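test_that("correlation Bayes factor matches high-precision reference values", {
  cases <- list(
    list(r = -0.36, n = 54, ref = BF_REFERENCE$cor_r036_n54),
    list(r = -589 / 1629, n = 54, ref = BF_REFERENCE$cor_rmed_n54),
    list(r = 0.48, n = 40, ref = BF_REFERENCE$cor_r048_n40),
    list(r = 0.5, n = 20, ref = BF_REFERENCE$cor_r05_n20),
    list(r = 0.3, n = 100, ref = BF_REFERENCE$cor_r03_n100),
    list(r = 0, n = 100, ref = BF_REFERENCE$cor_r0_n100)
  )
  for (cs in cases) {
    bf <- jzs_bf_cor(cs$r, cs$n)
    expect_equal(bf$bf10, cs$ref, tolerance = 1e-8)
    expect_equal(bf$bf01, 1 / bf$bf10, tolerance = 1e-12)
    expect_equal(bf$log_bf10, log(bf$bf10), tolerance = 1e-12)
    expect_true(is.finite(bf$integration_error_estimate))
  }
  # very large evidence stays accurate on the log scale
  expect_equal(jzs_bf_cor(0.9, 200)$log_bf10, log(BF_REFERENCE$cor_r09_n200),
               tolerance = 1e-8)
})

test_that("partial-correlation Bayes factor matches the reference and trivial identities", {
  bf <- jzs_bf_pcor(0.6084, 0.6084408, 1, 2, 40)
  expect_equal(bf$bf10, BF_REFERENCE$pcor_resumption, tolerance = 1e-8)
  # identical models carry no evidence either way
  expect_equal(jzs_bf_pcor(0.4, 0.4, 2, 2, 30)$bf10, 1, tolerance = 1e-9)
  expect_error(jzs_bf_pcor(0.5, 0.4, 1, 2, 30), "r0_sq <= r1_sq")
  expect_error(jzs_bf_pcor(0.1, 0.4, 2, 1, 30), "ordering")
  expect_error(jzs_bf_pcor(0.1, 0.4, 1, 2, 3), "exceed")
})

test_that("null model with no predictors reduces the partial test to the correlation test", {
  grid <- expand.grid(r = c(-0.8, -0.45, -0.1, 0.2, 0.6), n = c(5, 12, 40, 120))
  for (i in seq_len(nrow(grid))) {
    r <- grid$r[i]; n <- grid$n[i]
    bf_p <- jzs_bf_pcor(0, r^2, 0, 1, n)$bf10
    bf_c <- jzs_bf_cor(r, n)$bf10
    expect_equal(bf_p, bf_c, tolerance = 1e-8)
  }
})

test_that("quadrature agrees with an independent double-exponential integrator", {
  skip_if_not_installed("pracma")
  for (r in c(0, 0.3, 0.6, 0.9)) {
    for (n in c(3, 10, 50, 200)) {
      expect_equal(jzs_bf_cor(r, n)$bf10, jzs_bf_cor_reference(r, n),
                   tolerance = 1e-6,
                   label = sprintf("BF(r=%.1f, n=%d)", r, n))
    }
  }
})

test_that("Bayes factor depends on r only through r^2 and is monotone in |r| and n", {
  for (r in c(0.2, 0.55, 0.8))
    expect_identical(jzs_bf_cor(r, 30)$bf10, jzs_bf_cor(-r, 30)$bf10)

  rs <- seq(0, 0.9, by = 0.15)
  bfs <- vapply(rs, function(r) jzs_bf_cor(r, 40)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))

  ns <- c(5, 10, 20, 40, 80, 160)
  bfn <- vapply(ns, function(n) jzs_bf_cor(0.5, n)$bf10, numeric(1))
  expect_true(all(diff(bfn) > 0))
  # at r = 0 accumulating data supports the null
  bf0 <- vapply(ns, function(n) jzs_bf_cor(0, n)$bf10, numeric(1))
  expect_true(all(diff(bf0) < 0))
})

test_that("perfect correlation gives a divergent Bayes factor and large n stays finite in log space", {
  bf <- jzs_bf_cor(1, 10)
  expect_true(bf$divergent)
  expect_identical(bf$bf10, Inf)
  expect_identical(jzs_bf_cor(-1, 10)$bf10, Inf)
  expect_true(jzs_bf_pcor(0.2, 1, 1, 2, 30)$divergent)

  for (n in c(1e3, 1e4))
    expect_true(is.finite(jzs_bf_cor(0.1, n)$log_bf10))
  expect_true(is.finite(jzs_bf_cor(0.95, 1e4)$log_bf10))
})

test_that("fixed-g Bayes factor matches its closed form and reference value", {
  expect_equal(fixed_g_bf_cor(0.48, 40, 40)$bf10,
               BF_REFERENCE$fixedg_r048_n40_g40, tolerance = 1e-12)
  # null and alternative coincide as the prior collapses
  expect_equal(fixed_g_bf_cor(0.48, 40, 1e-12)$bf10, 1, tolerance = 1e-9)
  expect_error(fixed_g_bf_cor(0.48, 40, 0), "positive")
  expect_error(fixed_g_bf_cor(1, 40, 2), "strictly below 1")
})

test_that("inflating a fixed g drives the Bayes factor to zero (Lindley-Bartlett paradox)", {
  grid <- 10^(0:8)
  curve <- paradox_curve(0.48, 40, grid)
  expect_equal(nrow(curve), length(grid))
  # strictly decreasing beyond the maximum, heading to zero
  imax <- which.max(curve$bf10)
  expect_true(all(diff(curve$bf10[imax:nrow(curve)]) < 0))
  expect_lt(curve$bf10[nrow(curve)], 0.01 * curve$bf10[1])

  # with r = 0 the closed form is (1+g)^(-1/2), never above 1
  expect_true(all(paradox_curve(0, 25, grid)$bf10 <= 1))

  single <- paradox_curve(0.3, 30, 7)
  expect_equal(single$bf10, fixed_g_bf_cor(0.3, 30, 7)$bf10)
  expect_error(paradox_curve(0.3, 30, c(2, 1)), "increasing")
})
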