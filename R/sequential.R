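# Sequential Bayes-factor monitoring: because the Bayes factor quantifies
# evidence rather than long-run error rates, it may be recomputed as each
# observation arrives, with no correction for the sampling plan. No stopping
# rule is imposed here; the trajectory is reported as is.

#' Bayes-factor trajectory over accumulating observations
#'
#' For each prefix of the paired sample, from `min_n` observations up to the
#' full length, computes the sample correlation and its JZS Bayes factor
#' [jzs_bf_cor()]. Prefix windows in which either variable has zero variance
#' (the correlation is undefined) are skipped with a warning.
#'
#' @param x,y Numeric vectors of equal length, in arrival order.
#' @param min_n First sample size at which the Bayes factor is evaluated;
#'   at least 3. The default 5 avoids the noisiest, divergence-prone tiny
#'   windows while still showing early evidence.
#' @param rel.tol Quadrature tolerance passed to [jzs_bf_cor()].
#' @return An object of class `"bf_trajectory"`: a data frame with columns
#'   `n`, `r`, `bf10`, `log_bf10` and `label`, one row per evaluated prefix,
#'   with `min_n` stored as an attribute. The final row always equals the
#'   full-sample test.
#' @examples
#' d <- generate(synthetic_spec(n = 30, corr = corr2(0.8), seed = 11))
#' traj <- sequential_bf(d[[1]], d[[2]])
#' tail(traj, 1)
#' @export
sequential_bf <- function(x, y, min_n = 5L, rel.tol = 1e-10) {
  if (min_n < 3) stop("min_n must be at least 3", call. = FALSE)
  check_paired(x, y, min_n = min_n)
  sizes <- seq.int(min_n, length(x))
  rows <- vector("list", length(sizes))
  skipped <- integer(0)
  for (k in seq_along(sizes)) {
    m <- sizes[k]
    xs <- x[seq_len(m)]; ys <- y[seq_len(m)]
    if (stats::var(xs) == 0 || stats::var(ys) == 0) {
      skipped <- c(skipped, m)
      next
    }
    r <- pearson_r(xs, ys)
    bf <- jzs_bf_cor(r, m, rel.tol = rel.tol)
    rows[[k]] <- data.frame(n = m, r = r, bf10 = bf$bf10,
                            log_bf10 = bf$log_bf10,
                            label = classify_bf(bf$bf10)$label,
                            stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0)
    warning("skipped ", length(skipped),
            " prefix window(s) with zero variance (n = ",
            paste(skipped, collapse = ", "), ")", call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("no prefix window had nonzero variance in both variables",
         call. = FALSE)
  rownames(out) <- NULL
  attr(out, "min_n") <- min_n
  class(out) <- c("bf_trajectory", "data.frame")
  out
}

#' @export
print.bf_trajectory <- function(x, ...) {
  cat("Sequential JZS Bayes-factor trajectory (", nrow(x), " windows, n = ",
      x$n[1], "..", x$n[nrow(x)], ")\n", sep = "")
  final <- x[nrow(x), ]
  cat(sprintf("final: r = %.3f, BF10 = %.2f (%s)\n",
              final$r, final$bf10, final$label))
  invisible(x)
}

#' Serialize a Bayes-factor trajectory
#'
#' Writes a trajectory as tab-separated text (columns `n`, `bf10`,
#' `log_bf10`, `label`) or as a JSON array of records.
#'
#' @param traj A `"bf_trajectory"` from [sequential_bf()].
#' @param path Output file path; `""` writes TSV to stdout.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- traj[, c("n", "bf10", "log_bf10", "label")]
  if (format == "tsv") {
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(cols, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = I(17))
  }
  invisible(path)
}
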