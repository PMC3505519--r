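# High-level test runners combining the frequentist statistics, the JZS
# Bayes factor, evidence categories and posterior model probabilities into
# one result record. These back both the R interface and the command line.

new_cor_test <- function(r, n, prior_h1, rel.tol = 1e-10) {
  n <- as.integer(n)
  t <- t_from_r(r, n)
  df <- n - 2L
  bf <- jzs_bf_cor(r, n, rel.tol = rel.tol)
  out <- list(
    r = r, n = n, t = t, df = df, p = p_from_t(t, df),
    bf10 = bf$bf10, bf01 = bf$bf01, log_bf10 = bf$log_bf10,
    divergent = bf$divergent,
    label = classify_bf(bf$bf10)$label,
    probabilities = posterior_from_bf(bf$bf10, prior_h1)
  )
  class(out) <- c("cor_bf_test", "jzs_test")
  out
}

new_pcor_test <- function(r_partial, r0_sq, r1_sq, p0, p1, n, prior_h1,
                          rel.tol = 1e-10) {
  n <- as.integer(n)
  p0 <- as.integer(p0); p1 <- as.integer(p1)
  t <- t_from_partial_r(r_partial, n)
  df <- n - 3L
  bf <- jzs_bf_pcor(r0_sq, r1_sq, p0, p1, n, rel.tol = rel.tol)
  out <- list(
    r_partial = r_partial, n = n, r0_sq = r0_sq, r1_sq = r1_sq,
    p0 = p0, p1 = p1, t = t, df = df, p = p_from_t(t, df),
    bf10 = bf$bf10, bf01 = bf$bf01, log_bf10 = bf$log_bf10,
    divergent = bf$divergent,
    label = classify_bf(bf$bf10)$label,
    probabilities = posterior_from_bf(bf$bf10, prior_h1)
  )
  class(out) <- c("pcor_bf_test", "jzs_test")
  out
}

#' Correlation test from summary statistics
#'
#' Runs the full two-variable analysis — t statistic with \eqn{n-2} degrees
#' of freedom, two-sided p value, JZS Bayes factor, evidence category and
#' posterior model probabilities — from a sample correlation and sample size,
#' exactly as it would be computed from raw data having those statistics.
#'
#' @param r Sample correlation.
#' @param n Sample size, at least 3.
#' @param prior_h1 Prior probability of the alternative hypothesis.
#' @param rel.tol Quadrature tolerance.
#' @return A list of class `"cor_bf_test"` with fields `r`, `n`, `t`, `df`,
#'   `p`, `bf10`, `bf01`, `log_bf10`, `divergent`, `label` and
#'   `probabilities`.
#' @examples
#' run_corr_from_stats(0.48, 40)
#' @export
run_corr_from_stats <- function(r, n, prior_h1 = 0.5, rel.tol = 1e-10) {
  new_cor_test(r, n, prior_h1, rel.tol)
}

#' Partial-correlation test from summary statistics
#'
#' Runs the full three-variable analysis from the three pairwise sample
#' correlations. The partial correlation between X and Y given the control Z
#' is tested as a nested-regression comparison with X as the dependent
#' variable: the null model contains Z alone (\eqn{p_0 = 1},
#' \eqn{R_0^2 = r_{XZ}^2}), the alternative adds Y (\eqn{p_1 = 2},
#' \eqn{R_1^2 = r_{XY|Z}^2 (1 - r_{XZ}^2) + r_{XZ}^2}).
#'
#' @param r_xy,r_xz,r_yz Pairwise sample correlations between the two tested
#'   variables (X, Y) and the control (Z).
#' @param n Sample size, at least 4.
#' @param prior_h1 Prior probability of the alternative hypothesis.
#' @param rel.tol Quadrature tolerance.
#' @return A list of class `"pcor_bf_test"` with fields `r_partial`, `n`,
#'   `r0_sq`, `r1_sq`, `p0`, `p1`, `t`, `df`, `p`, `bf10`, `bf01`,
#'   `log_bf10`, `divergent`, `label` and `probabilities`.
#' @examples
#' run_pcorr_from_stats(.51, -.78, -.66, 40)
#' @export
run_pcorr_from_stats <- function(r_xy, r_xz, r_yz, n, prior_h1 = 0.5,
                                 rel.tol = 1e-10) {
  rp <- partial_r(r_xy, r_xz, r_yz)
  r0_sq <- r_squared(r_xz)
  r1_sq <- r1_squared_from_partial(rp, r_xz)
  new_pcor_test(rp, r0_sq, r1_sq, p0 = 1, p1 = 2, n = n,
                prior_h1 = prior_h1, rel.tol = rel.tol)
}

#' Coefficient-of-determination form of the partial-correlation test
#'
#' For inputs printed as coefficients of determination rather than
#' correlations: runs the nested-model JZS comparison directly from
#' \eqn{R_0^2, R_1^2, p_0, p_1, n}. The implied partial correlation
#' \eqn{\sqrt{(R_1^2 - R_0^2)/(1 - R_0^2)}} carries no sign, so the t
#' statistic is reported with the sign of `sign_r_partial`.
#'
#' @param r0_sq,r1_sq,p0,p1 Nested-model summaries as in [jzs_bf_pcor()].
#' @param n Sample size.
#' @param sign_r_partial Sign (+1/-1) of the partial correlation.
#' @param prior_h1 Prior probability of the alternative hypothesis.
#' @param rel.tol Quadrature tolerance.
#' @return As [run_pcorr_from_stats()].
#' @examples
#' run_pcorr_from_r2(0.6084, 0.6084408, 1, 2, 40, sign_r_partial = -1)
#' @export
run_pcorr_from_r2 <- function(r0_sq, r1_sq, p0, p1, n, sign_r_partial = 1,
                              prior_h1 = 0.5, rel.tol = 1e-10) {
  rp <- sign(sign_r_partial) * sqrt((r1_sq - r0_sq) / (1 - r0_sq))
  new_pcor_test(rp, r0_sq, r1_sq, p0, p1, n, prior_h1, rel.tol)
}

#' Correlation test from a delimited data file or data frame
#'
#' Reads two numeric columns (comma- or tab-separated text with a header, or
#' an in-memory data frame), drops incomplete rows with a message, and runs
#' the same analysis as [run_corr_from_stats()] on the resulting sample.
#'
#' @param data Path to a CSV/TSV file, or a data frame.
#' @param columns Character vector of the two column names (default: first
#'   two columns).
#' @param prior_h1 Prior probability of the alternative hypothesis.
#' @param sep Field separator; `NULL` sniffs comma vs tab from the header.
#' @param rel.tol Quadrature tolerance.
#' @return A `"cor_bf_test"` (see [run_corr_from_stats()]).
#' @examples
#' d <- fixture_facebook(seed = 1, exact = TRUE)
#' run_corr_from_data(d)
#' @export
run_corr_from_data <- function(data, columns = NULL, prior_h1 = 0.5,
                               sep = NULL, rel.tol = 1e-10) {
  d <- resolve_columns(data, columns, k = 2L, sep = sep)
  run_corr_from_stats(pearson_r(d[[1]], d[[2]]), nrow(d),
                      prior_h1 = prior_h1, rel.tol = rel.tol)
}

#' Partial-correlation test from a delimited data file or data frame
#'
#' Reads three numeric columns ordered (X, Y, Z) with Z the control variable,
#' drops incomplete rows, computes the three pairwise correlations and runs
#' [run_pcorr_from_stats()].
#'
#' @inheritParams run_corr_from_data
#' @return A `"pcor_bf_test"` (see [run_pcorr_from_stats()]).
#' @examples
#' d <- fixture_resumption(seed = 1, exact = TRUE)
#' run_pcorr_from_data(d)
#' @export
run_pcorr_from_data <- function(data, columns = NULL, prior_h1 = 0.5,
                                sep = NULL, rel.tol = 1e-10) {
  d <- resolve_columns(data, columns, k = 3L, sep = sep)
  x <- d[[1]]; y <- d[[2]]; z <- d[[3]]
  run_pcorr_from_stats(pearson_r(x, y), pearson_r(x, z), pearson_r(y, z),
                       nrow(d), prior_h1 = prior_h1, rel.tol = rel.tol)
}

resolve_columns <- function(data, columns, k, sep = NULL) {
  d <- if (is.data.frame(data)) data else read_corr_data(data, sep = sep)
  if (is.null(columns)) columns <- names(d)[seq_len(k)]
  if (length(columns) != k)
    stop("expected ", k, " column names", call. = FALSE)
  missing_cols <- setdiff(columns, names(d))
  if (length(missing_cols) > 0)
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- d[, columns, drop = FALSE]
  for (cl in columns)
    if (!is.numeric(d[[cl]]))
      stop("column '", cl, "' is not numeric", call. = FALSE)
  keep <- stats::complete.cases(d)
  if (any(!keep))
    message("dropped ", sum(!keep), " incomplete row(s)")
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < k + 1)
    stop("fewer than ", k + 1, " complete rows", call. = FALSE)
  d
}

#' Read a delimited data file
#'
#' Reads UTF-8 comma- or tab-separated text with a header row. When `sep` is
#' `NULL` the separator is sniffed from the header line (tab wins if present,
#' else comma).
#'
#' @param path File path.
#' @param sep Field separator, or `NULL` to sniff.
#' @return A data frame.
#' @export
read_corr_data <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, encoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

# ---- printing and serialization -------------------------------------------

#' @export
print.cor_bf_test <- function(x, ...) {
  cat("JZS Bayesian correlation test\n")
  cat(sprintf("  r = %.2f, n = %d\n", x$r, as.integer(x$n)))
  cat(sprintf("  t(%d) = %.2f, two-sided p = %.2f\n",
              as.integer(x$df), x$t, x$p))
  cat(sprintf("  BF10 = %.2f, BF01 = %.2f\n", x$bf10, x$bf01))
  cat(sprintf("  %s; p(H1|Y) = %.2f (prior %.2f)\n", x$label,
              x$probabilities$posterior_h1, x$probabilities$prior_h1))
  invisible(x)
}

#' @export
print.pcor_bf_test <- function(x, ...) {
  cat("JZS Bayesian partial-correlation test\n")
  cat(sprintf("  partial r = %.2f, n = %d\n", x$r_partial, as.integer(x$n)))
  cat(sprintf("  R0^2 = %.4f (p0 = %d), R1^2 = %.7f (p1 = %d)\n",
              x$r0_sq, as.integer(x$p0), x$r1_sq, as.integer(x$p1)))
  cat(sprintf("  t(%d) = %.2f, two-sided p = %.2f\n",
              as.integer(x$df), x$t, x$p))
  cat(sprintf("  BF10 = %.2f, BF01 = %.2f\n", x$bf10, x$bf01))
  cat(sprintf("  %s; p(H1|Y) = %.2f (prior %.2f)\n", x$label,
              x$probabilities$posterior_h1, x$probabilities$prior_h1))
  invisible(x)
}

#' Serialize a test result
#'
#' `result_to_json()` emits a single JSON record at full numeric precision;
#' `result_to_tsv()` emits a two-line (header + values) tab-separated record.
#' Parsing the JSON back recovers every numeric field exactly.
#'
#' @param x A `"cor_bf_test"` or `"pcor_bf_test"` result.
#' @param path Output file, or `NULL` to return the text.
#' @return The serialized text (invisibly when written to `path`).
#' @export
result_to_json <- function(x, path = NULL) {
  rec <- result_record(x)
  txt <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                          null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname result_to_json
#' @export
result_to_tsv <- function(x, path = NULL) {
  rec <- result_record(x)
  flat <- rec
  flat$probabilities <- NULL
  flat <- c(flat, rec$probabilities)
  txt <- paste(
    paste(names(flat), collapse = "\t"),
    paste(vapply(flat, function(v) format(v, digits = 17), character(1)),
          collapse = "\t"),
    sep = "\n"
  )
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

result_record <- function(x) {
  stopifnot(inherits(x, "jzs_test"))
  rec <- unclass(x)
  rec$probabilities <- unclass(rec$probabilities)
  rec$kind <- if (inherits(x, "cor_bf_test")) "correlation" else
    "partial_correlation"
  rec
}
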