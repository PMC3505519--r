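# JZS (Jeffreys-Zellner-Siow) Bayes factors for correlation and partial
# correlation, computed as nested linear-model comparisons under a
# mixture-of-g prior: Zellner's g-prior on the regression coefficients with an
# inverse-gamma(1/2, n/2) prior on g. Marginalizing everything but g leaves a
# single integral over g in (0, Inf), which is evaluated numerically.

# Log of the g-integrand shared by all model marginals:
#   (1+g)^((n-1-p)/2) * [1 + (1-R2) g]^(-(n-1)/2) * g^(-3/2) * exp(-n/(2g))
# p is the number of regression coefficients of the model, R2 its coefficient
# of determination.
jzs_log_integrand <- function(g, r2, p, n) {
  (n - 1 - p) / 2 * log1p(g) -
    (n - 1) / 2 * log1p((1 - r2) * g) -
    1.5 * log(g) - n / (2 * g)
}

# One JZS model marginal on the log scale (up to the common constant):
#   log Integral_0^Inf integrand dg.
# The substitution u = g/(1+g) maps (0, Inf) to (0, 1); the integrand is
# evaluated in log space and rescaled by its maximum so that exp() neither
# overflows nor underflows for large n. Returns log value plus the achieved
# absolute-error estimate of the quadrature (on the original scale, as the
# log of the absolute error).
jzs_log_integral <- function(r2, p, n, rel.tol = 1e-10) {
  logf_u <- function(u) {
    g <- u / (1 - u)
    jzs_log_integrand(g, r2, p, n) - 2 * log1p(-u)
  }
  # locate the maximum of the log integrand: coarse grid + local refinement
  eps <- 1e-12
  grid <- seq(eps, 1 - eps, length.out = 257)
  lg <- logf_u(grid)
  i <- which.max(lg)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(logf_u, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  m <- max(opt$objective, lg[i])
  if (!is.finite(m))
    stop("JZS integrand maximum is not finite", call. = FALSE)
  quad <- stats::integrate(function(u) exp(logf_u(u) - m), 0, 1,
                           rel.tol = rel.tol, abs.tol = 0,
                           subdivisions = 500L)
  if (quad$message != "OK")
    stop("JZS quadrature failed to converge (", quad$message,
         "); achieved abs.error ", format(quad$abs.error), call. = FALSE)
  list(log_value = log(quad$value) + m,
       log_abs_error = log(quad$abs.error) + m)
}

# log of Integral g^(-3/2) exp(-n/(2g)) dg = log Gamma(1/2) - log sqrt(n/2);
# the null marginal of the plain correlation test in closed form.
log_null_integral <- function(n) lgamma(0.5) - 0.5 * log(n / 2)

new_bf_result <- function(log_bf10, error = NA_real_, divergent = FALSE,
                          method = "jzs-quadrature") {
  bf10 <- if (divergent) Inf else exp(log_bf10)
  out <- list(
    bf10 = bf10,
    bf01 = if (divergent) 0 else exp(-log_bf10),
    log_bf10 = if (divergent) Inf else log_bf10,
    integration_error_estimate = error,
    divergent = divergent,
    method = method
  )
  class(out) <- "bf_result"
  out
}

#' @export
print.bf_result <- function(x, ...) {
  if (x$divergent) {
    cat("Bayes factor BF10: Inf (divergent marginal-likelihood ratio)\n")
  } else {
    cat(sprintf("Bayes factor BF10: %.2f (BF01 = %.2f, log BF10 = %.4f)\n",
                x$bf10, x$bf01, x$log_bf10))
  }
  invisible(x)
}

#' JZS Bayes factor for the presence of a correlation
#'
#' Bayes factor \eqn{BF_{10}} comparing the regression model with the single
#' predictor against the intercept-only null, under the JZS mixture-of-g
#' prior:
#' \deqn{BF_{10} = \frac{(n/2)^{1/2}}{\Gamma(1/2)} \int_0^\infty
#'   (1+g)^{(n-2)/2} \left[1 + (1-r^2) g\right]^{-(n-1)/2}
#'   g^{-3/2} e^{-n/(2g)} \, dg.}
#' The only inputs are the sample correlation \eqn{r} and the sample size
#' \eqn{n}; the result depends on \eqn{r} only through \eqn{r^2}.
#'
#' @param r Sample correlation in \eqn{[-1, 1]}.
#' @param n Sample size, \eqn{n \ge 3}.
#' @param rel.tol Relative tolerance passed to the quadrature.
#' @return An object of class `"bf_result"`: a list with `bf10`, `bf01`,
#'   `log_bf10`, `integration_error_estimate`, `divergent` and `method`.
#'   `|r| = 1` gives a genuinely unbounded marginal-likelihood ratio,
#'   returned as `bf10 = Inf` with `divergent = TRUE`.
#' @examples
#' jzs_bf_cor(-589 / 1629, 54)
#' jzs_bf_cor(0.48, 40)
#' @export
jzs_bf_cor <- function(r, n, rel.tol = 1e-10) {
  check_correlation(r)
  if (n < 3) stop("n must be at least 3", call. = FALSE)
  if (abs(r) == 1) return(new_bf_result(Inf, divergent = TRUE))
  alt <- jzs_log_integral(r^2, p = 1, n = n, rel.tol = rel.tol)
  log_bf <- alt$log_value - log_null_integral(n)
  new_bf_result(log_bf, error = exp(alt$log_abs_error - log_null_integral(n)))
}

#' JZS Bayes factor for the presence of a partial correlation
#'
#' Bayes factor \eqn{BF_{10}} for adding one predictor to a regression that
#' already contains the control variable(s), computed as the ratio of two JZS
#' model marginals:
#' \deqn{BF_{10} = \frac{\int_0^\infty (1+g)^{(n-1-p_1)/2}
#'   [1+(1-R_1^2)g]^{-(n-1)/2} g^{-3/2} e^{-n/(2g)} dg}
#'   {\int_0^\infty (1+g)^{(n-1-p_0)/2}
#'   [1+(1-R_0^2)g]^{-(n-1)/2} g^{-3/2} e^{-n/(2g)} dg}.}
#' Inputs are the two coefficients of determination, the regression
#' coefficient counts \eqn{p_0 < p_1}, and the sample size.
#'
#' @param r0_sq,r1_sq Coefficients of determination of the null and
#'   alternative models, \eqn{0 \le R_0^2 \le R_1^2 \le 1}.
#' @param p0,p1 Number of regression coefficients (excluding intercept) of
#'   each model, \eqn{0 \le p_0 \le p_1}; equal counts with equal
#'   \eqn{R^2} describe identical models and give \eqn{BF_{10} = 1}.
#' @param n Sample size; must exceed \eqn{p_1 + 1}.
#' @param rel.tol Relative tolerance passed to the quadrature.
#' @return An object of class `"bf_result"` (see [jzs_bf_cor()]).
#' @examples
#' jzs_bf_pcor(0.6084, 0.6084408, 1, 2, 40)
#' @export
jzs_bf_pcor <- function(r0_sq, r1_sq, p0, p1, n, rel.tol = 1e-10) {
  if (r0_sq < 0 || r1_sq > 1 || r0_sq > r1_sq)
    stop("need 0 <= r0_sq <= r1_sq <= 1", call. = FALSE)
  if (p0 < 0 || p1 < p0)
    stop("invalid ordering: need 0 <= p0 <= p1", call. = FALSE)
  if (n <= p1 + 1)
    stop("n must exceed p1 + 1", call. = FALSE)
  if (r1_sq == 1) return(new_bf_result(Inf, divergent = TRUE))
  num <- jzs_log_integral(r1_sq, p = p1, n = n, rel.tol = rel.tol)
  den <- if (p0 == 0 && r0_sq == 0) {
    list(log_value = log_null_integral(n), log_abs_error = -Inf)
  } else {
    jzs_log_integral(r0_sq, p = p0, n = n, rel.tol = rel.tol)
  }
  log_bf <- num$log_value - den$log_value
  err <- exp(num$log_abs_error - den$log_value) +
    exp(log_bf + den$log_abs_error - den$log_value)
  new_bf_result(log_bf, error = err)
}

#' Fixed-g Zellner Bayes factor for a correlation
#'
#' The Bayes factor conditional on a single fixed value of the prior scale
#' \eqn{g} (i.e. the JZS integrand ratio with a point mass on \eqn{g} instead
#' of the mixture prior):
#' \deqn{BF_{10}(g) = (1+g)^{(n-2)/2} \left[1+(1-r^2) g\right]^{-(n-1)/2},}
#' evaluated in log space. As \eqn{g \to \infty} this tends to 0 for any
#' fixed data — the Jeffreys-Lindley-Bartlett paradox.
#'
#' @param r Sample correlation, \eqn{|r| < 1}.
#' @param n Sample size, \eqn{n \ge 3}.
#' @param g Positive prior scale; `g = n` is the unit-information prior.
#' @return An object of class `"bf_result"` with `method = "fixed-g"`.
#' @examples
#' fixed_g_bf_cor(0.48, 40, g = 40)
#' @export
fixed_g_bf_cor <- function(r, n, g) {
  check_correlation(r)
  if (abs(r) == 1) stop("|r| must be strictly below 1", call. = FALSE)
  if (n < 3) stop("n must be at least 3", call. = FALSE)
  if (!is.numeric(g) || g <= 0) stop("g must be positive", call. = FALSE)
  log_bf <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g)
  new_bf_result(log_bf, error = 0, method = "fixed-g")
}

#' Bayes factor as a function of the fixed prior scale g
#'
#' Evaluates [fixed_g_bf_cor()] over a grid of g values, tracing how the
#' evidence against the null can be driven toward zero by inflating the prior
#' scale (the Jeffreys-Lindley-Bartlett paradox).
#'
#' @param r Sample correlation, \eqn{|r| < 1}.
#' @param n Sample size.
#' @param g_grid Increasing positive vector of g values.
#' @return A data frame with columns `g`, `bf10` and `log_bf10`.
#' @examples
#' paradox_curve(0.48, 40, g_grid = 10^(0:8))
#' @export
paradox_curve <- function(r, n, g_grid) {
  if (length(g_grid) == 0 || any(g_grid <= 0) || is.unsorted(g_grid,
                                                             strictly = TRUE))
    stop("g_grid must be a nonempty strictly increasing positive vector",
         call. = FALSE)
  res <- lapply(g_grid, function(g) fixed_g_bf_cor(r, n, g))
  data.frame(
    g = g_grid,
    bf10 = vapply(res, `[[`, numeric(1), "bf10"),
    log_bf10 = vapply(res, `[[`, numeric(1), "log_bf10")
  )
}
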