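# Reference values and independent integrators used across the test files.

# High-precision reference Bayes factors, computed once with an adaptive
# quadrature at 50-digit working precision (mpmath) on the untransformed
# integrand over (0, Inf), split at several interior nodes. Frozen here so
# the suite needs no multiprecision dependency at run time.
BF_REFERENCE <- list(
  cor_r036_n54      = 3.72095823308331,    # r = -0.36,      n = 54
  cor_rmed_n54      = 3.8471460165106,     # r = -589/1629,  n = 54
  cor_r048_n40      = 16.1159045853743,    # r = 0.48,       n = 40
  cor_r05_n20       = 2.08267393807837,    # r = 0.5,        n = 20
  cor_r03_n100      = 7.69737581146272,    # r = 0.3,        n = 100
  cor_r09_n200      = 6.30594482614329e69, # r = 0.9,        n = 200
  cor_r0_n100       = 0.079013388202772,   # r = 0,          n = 100
  pcor_resumption   = 0.127169907302353,   # R0^2=.6084, R1^2=.6084408, n=40
  fixedg_r048_n40_g40 = 22.3782701713706   # r = 0.48, n = 40, g = 40
)

# Independent brute-force evaluation of the JZS marginal-likelihood ratio:
# double-exponential quadrature (pracma::quadinf) of the raw integrand on
# (0, Inf), in linear space, no substitution — a different algorithm and
# parameterization from the package's path.
jzs_bf_cor_reference <- function(r, n) {
  logf <- function(g)
    (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
      1.5 * log(g) - n / (2 * g)
  # constant rescaling so the quadrature works at magnitude ~1 (the
  # double-exponential rule's stopping test is absolute)
  k <- max(logf(10^seq(-3, 8, length.out = 400)))
  integrand <- function(g) {
    v <- exp(logf(g) - k)
    v[!is.finite(v) | g <= 0] <- 0   # integrand vanishes at g -> 0+
    v
  }
  sqrt(n / 2) / gamma(0.5) * exp(k) *
    pracma::quadinf(integrand, 0, Inf, tol = 1e-10)$Q
}

# Regression-residual definition of the partial correlation: correlate the
# least-squares residuals of x ~ z and y ~ z.
partial_r_residual_reference <- function(x, y, z) {
  cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
}
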