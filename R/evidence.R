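# Verbal evidence categories (Jeffreys' scale, with "not worth more than a
# bare mention" relabelled "Anecdotal") and posterior model probabilities.

.evidence_breaks <- c(3, 10, 30, 100)
.evidence_names <- c("Anecdotal", "Substantial", "Strong", "Very Strong",
                     "Decisive")

#' Verbal evidence category for a Bayes factor
#'
#' Maps \eqn{BF_{10}} onto Jeffreys' coarse category scheme: Anecdotal
#' (1-3), Substantial (3-10), Strong (10-30), Very Strong (30-100) and
#' Decisive (>100) evidence for \eqn{H_1}, the mirror-image reciprocal ranges
#' for \eqn{H_0}, and "No evidence" at exactly 1. Values falling exactly on a
#' boundary (3, 10, 30, 100 and reciprocals) are assigned to the stronger
#' adjacent category.
#'
#' @param bf10 Positive Bayes factor (may be `Inf` or 0).
#' @return An object of class `"bf_evidence"`: list with `category` (one of
#'   the ten categories or `"No evidence"`), `direction` (`"H1"`, `"H0"` or
#'   `"none"`) and `label`, the full sentence-style label used in printed and
#'   serialized output.
#' @examples
#' classify_bf(3.86)$label   # "Substantial evidence for H1"
#' classify_bf(0.13)$label   # "Substantial evidence for H0"
#' @export
classify_bf <- function(bf10) {
  if (!is.numeric(bf10) || length(bf10) != 1L || is.na(bf10) || bf10 < 0)
    stop("bf10 must be a single nonnegative number", call. = FALSE)
  if (bf10 == 1) {
    out <- list(category = "No evidence", direction = "none",
                label = "No evidence")
    class(out) <- "bf_evidence"
    return(out)
  }
  direction <- if (bf10 > 1) "H1" else "H0"
  magnitude <- if (bf10 > 1) bf10 else 1 / bf10
  # boundary values belong to the stronger category
  idx <- sum(magnitude >= .evidence_breaks) + 1L
  category <- .evidence_names[idx]
  out <- list(category = category, direction = direction,
              label = sprintf("%s evidence for %s", category, direction))
  class(out) <- "bf_evidence"
  out
}

#' @export
print.bf_evidence <- function(x, ...) {
  cat(x$label, "\n")
  invisible(x)
}

#' Posterior model probabilities from a Bayes factor
#'
#' Updates prior model odds by the Bayes factor:
#' \deqn{\frac{p(H_1 \mid Y)}{p(H_0 \mid Y)} = BF_{10} \times
#'   \frac{p(H_1)}{p(H_0)}.}
#'
#' @param bf10 Positive Bayes factor (may be `Inf`).
#' @param prior_h1 Prior probability of the alternative, strictly in (0, 1).
#' @return A list of class `"model_probabilities"` with `prior_h1`,
#'   `prior_h0`, `posterior_h1`, `posterior_h0`.
#' @examples
#' posterior_from_bf(4, 0.5)$posterior_h1   # 0.8
#' @export
posterior_from_bf <- function(bf10, prior_h1 = 0.5) {
  if (!is.numeric(bf10) || length(bf10) != 1L || is.na(bf10) || bf10 <= 0)
    stop("bf10 must be a single positive number", call. = FALSE)
  if (prior_h1 <= 0 || prior_h1 >= 1)
    stop("prior_h1 must be strictly between 0 and 1", call. = FALSE)
  odds <- bf10 * prior_h1 / (1 - prior_h1)
  posterior_h1 <- if (is.infinite(odds)) 1 else odds / (1 + odds)
  out <- list(prior_h1 = prior_h1, prior_h0 = 1 - prior_h1,
              posterior_h1 = posterior_h1, posterior_h0 = 1 - posterior_h1)
  class(out) <- "model_probabilities"
  out
}

#' @export
print.model_probabilities <- function(x, ...) {
  cat(sprintf("p(H1) = %.3f -> p(H1|Y) = %.3f\n", x$prior_h1, x$posterior_h1))
  invisible(x)
}
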