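#' Sample moments of a paired sample
#'
#' Computes the summary quantities that define the Pearson correlation:
#' sample size, means, unbiased variances, and the centered cross-product sum
#' \eqn{\sum_i (x_i - \bar x)(y_i - \bar y)}.
#'
#' @param x,y Numeric vectors of equal length (\eqn{n \ge 2}).
#' @return A list of class `"sample_moments"` with elements `n`, `mean_x`,
#'   `mean_y`, `var_x`, `var_y` (unbiased, \eqn{n-1} denominator) and
#'   `cross_sum`.
#' @examples
#' sample_moments(1:4, c(1, 3, 2, 5))
#' @export
sample_moments <- function(x, y) {
  check_paired(x, y, min_n = 2L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  out <- list(
    n = n, mean_x = mx, mean_y = my,
    var_x = stats::var(x), var_y = stats::var(y),
    cross_sum = sum((x - mx) * (y - my))
  )
  class(out) <- "sample_moments"
  out
}

#' Pearson product-moment correlation
#'
#' The sample correlation coefficient
#' \deqn{r = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}{(n-1)\, s_X s_Y},}
#' with unbiased sample standard deviations \eqn{s_X, s_Y}.
#'
#' @param x,y Numeric vectors of equal length, \eqn{n \ge 3}, each with
#'   nonzero variance.
#' @return The correlation, a scalar in \eqn{[-1, 1]}.
#' @examples
#' pearson_r(1:4, c(2, 4, 6, 8))   # 1
#' pearson_r(1:4, c(1, 3, 2, 5))
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  m <- sample_moments(x, y)
  if (m$var_x <= 0 || m$var_y <= 0)
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  r <- m$cross_sum / ((m$n - 1) * sqrt(m$var_x) * sqrt(m$var_y))
  # guard rounding just past the boundary
  max(-1, min(1, r))
}

#' Partial correlation from three pairwise correlations
#'
#' Correlation between X and Y after removing the linear effect of a control
#' variable Z:
#' \deqn{r_{XY|Z} = \frac{r_{XY} - r_{XZ} r_{YZ}}
#'   {\sqrt{(1 - r_{XZ}^2)(1 - r_{YZ}^2)}}.}
#'
#' An input triple that is not a valid correlation matrix (not positive
#' semidefinite) can push the formula outside \eqn{[-1, 1]}; that is reported
#' as an error rather than clamped.
#'
#' @param r_xy,r_xz,r_yz Pairwise sample correlations; `r_xz` and `r_yz` must
#'   be strictly inside \eqn{(-1, 1)}.
#' @return The partial correlation \eqn{r_{XY|Z}}.
#' @examples
#' partial_r(.51, -.78, -.66)   # ~ -0.0102
#' @export
partial_r <- function(r_xy, r_xz, r_yz) {
  for (r in c(r_xy, r_xz, r_yz)) check_correlation(r)
  if (abs(r_xz) >= 1 || abs(r_yz) >= 1)
    stop("partial correlation undefined: a control correlation is +/-1",
         call. = FALSE)
  rp <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (abs(rp) > 1 + 1e-12)
    stop("inconsistent correlation triple (not positive semidefinite): ",
         "partial correlation ", format(rp), " outside [-1, 1]", call. = FALSE)
  max(-1, min(1, rp))
}

#' t statistic for a correlation
#'
#' \deqn{t = r \sqrt{\frac{n-2}{1-r^2}},} with \eqn{n - 2} degrees of freedom
#' under the null hypothesis \eqn{\rho = 0}.
#'
#' @param r Sample correlation.
#' @param n Sample size, \eqn{n \ge 3}.
#' @return The t statistic; signed infinity (with a warning) when
#'   \eqn{|r| = 1}.
#' @examples
#' t_from_r(-589 / 1629, 54)   # -2.80
#' @export
t_from_r <- function(r, n) {
  check_correlation(r)
  if (n < 3) stop("n must be at least 3", call. = FALSE)
  if (abs(r) == 1) {
    warning("|r| = 1: t statistic is infinite", call. = FALSE)
    return(sign(r) * Inf)
  }
  r * sqrt((n - 2) / (1 - r^2))
}

#' t statistic for a partial correlation
#'
#' \deqn{t = r_{XY|Z} \sqrt{\frac{n-3}{1-r_{XY|Z}^2}},} with \eqn{n - 3}
#' degrees of freedom (one lost to the control variable).
#'
#' @param r_partial Sample partial correlation.
#' @param n Sample size, \eqn{n \ge 4}.
#' @return The t statistic.
#' @examples
#' t_from_partial_r(partial_r(.51, -.78, -.66), 40)   # -0.06
#' @export
t_from_partial_r <- function(r_partial, n) {
  check_correlation(r_partial)
  if (n < 4) stop("n must be at least 4 for a partial-correlation test",
                  call. = FALSE)
  if (abs(r_partial) == 1) {
    warning("|r| = 1: t statistic is infinite", call. = FALSE)
    return(sign(r_partial) * Inf)
  }
  r_partial * sqrt((n - 3) / (1 - r_partial^2))
}

#' Two-sided p value from a t statistic
#'
#' @param t t statistic.
#' @param df Degrees of freedom, \eqn{\ge 1}.
#' @return The two-sided tail probability \eqn{2 P(T_{df} \ge |t|)}.
#' @examples
#' p_from_t(t_from_r(-589 / 1629, 54), 52)
#' @export
p_from_t <- function(t, df) {
  if (df < 1) stop("df must be at least 1", call. = FALSE)
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Coefficient of determination
#'
#' For a simple regression, \eqn{R^2} is the square of the sample correlation;
#' equivalently \eqn{R^2 = 1 - SS_{err}/SS_{tot}} from residual and total sums
#' of squares.
#'
#' @param r Sample correlation (used when sums of squares are not supplied).
#' @param ss_err,ss_tot Residual and total sums of squares; when both are
#'   given they define \eqn{R^2} and `r` is ignored.
#' @return \eqn{R^2 \in [0, 1]}.
#' @examples
#' r_squared(-.78)                    # 0.6084
#' r_squared(ss_err = 2, ss_tot = 8)  # 0.75
#' @export
r_squared <- function(r = NULL, ss_err = NULL, ss_tot = NULL) {
  if (!is.null(ss_err) && !is.null(ss_tot)) {
    if (ss_err < 0 || ss_tot <= 0)
      stop("sums of squares must be nonnegative (ss_tot positive)",
           call. = FALSE)
    return(1 - ss_err / ss_tot)
  }
  if (is.null(r)) stop("supply either r or both sums of squares", call. = FALSE)
  check_correlation(r)
  r^2
}

#' Alternative-model R-squared from a partial correlation
#'
#' For the nested comparison behind the partial-correlation test, the
#' alternative model's coefficient of determination is
#' \deqn{R_1^2 = r_{XY|Z}^2 (1 - r_{XZ}^2) + r_{XZ}^2,}
#' where \eqn{r_{XZ}} is the correlation between the dependent variable and
#' the control variable (the null model's sole predictor, so
#' \eqn{R_0^2 = r_{XZ}^2}).
#'
#' @param r_partial Sample partial correlation.
#' @param r_control Correlation between dependent and control variable.
#' @return \eqn{R_1^2}, always \eqn{\ge r_{control}^2}.
#' @examples
#' r1_squared_from_partial(partial_r(.51, -.78, -.66), -.78)  # 0.6084408
#' @export
r1_squared_from_partial <- function(r_partial, r_control) {
  check_correlation(r_partial)
  check_correlation(r_control)
  r_partial^2 * (1 - r_control^2) + r_control^2
}

# ---- input checks ----------------------------------------------------------

check_paired <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("inputs must be numeric", call. = FALSE)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop("need at least ", min_n, " paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values present; remove incomplete pairs first",
         call. = FALSE)
  invisible(TRUE)
}

check_correlation <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1)
    stop("correlation must be a single value in [-1, 1]", call. = FALSE)
  invisible(TRUE)
}
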