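#' Audic-Claverie tail probability for a count difference
#'
#' Exact tail probability for observing count `y` in a library of size `n2`
#' given count `x` in a library of size `n1`, under the Audic-Claverie
#' posterior
#' \deqn{p(y|x) = (n2/n1)^y \frac{(x+y)!}{x!\,y!\,(1+n2/n1)^{x+y+1}}.}
#' This distribution is a negative binomial with size `x + 1` and success
#' probability `n1/(n1+n2)`, which is how the tails are evaluated — exactly
#' and without overflow for large counts. The two-sided p-value is twice the
#' smaller of the lower tail `P(Y <= y)` and upper tail `P(Y >= y)`, capped
#' at 1.
#'
#' @param x,y observed counts (non-negative integers, vectorised).
#' @param n1,n2 library sizes (positive).
#' @param two_sided return the two-sided p-value (default) or the point
#'   probability `p(y|x)` when `FALSE`.
#' @return numeric vector of probabilities.
#' @examples
#' audic_claverie_p(0, 0, 100, 100)                     # 1 (two-sided)
#' audic_claverie_p(5, 0, 100, 100, two_sided = FALSE)  # 1/64
#' @export
audic_claverie_p <- function(x, y, n1, n2, two_sided = TRUE) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  prob <- n1 / (n1 + n2)
  if (!two_sided) return(stats::dnbinom(y, size = x + 1, prob = prob))
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- 1 - stats::pnbinom(y - 1, size = x + 1, prob = prob)
  pmin(1, 2 * pmin(lower, upper))
}

#' Call preferred/avoided items against expected frequencies
#'
#' For each item the expected count is `round(n * expected_freq)`; the
#' Audic-Claverie two-sided p-value compares the observed and expected
#' counts as two libraries of equal size `n`, and the log2 observed/expected
#' ratio is computed on counts with a +0.5 continuity correction applied
#' when either count is zero. An item is `preferred` when
#' `p < p_thresh` and `log2_ratio >= log2_cutoff`, `avoided` when
#' `p < p_thresh` and `log2_ratio <= -log2_cutoff`, otherwise `unbiased`.
#' Reported p-values are floored at `p_floor`.
#'
#' @param observed named integer vector of observed counts.
#' @param expected_freq named numeric vector of expected frequencies
#'   (same names; must sum to 1 within 1e-6).
#' @param n library size (defaults to `sum(observed)`).
#' @param p_thresh significance threshold (default 0.01).
#' @param log2_cutoff absolute log2 ratio cutoff (default 1.5, i.e. 3-fold).
#' @param p_floor reporting floor for p-values (default 1e-10).
#' @return data frame of class `bias_calls`: item, obs, exp (rounded
#'   expected count), log2_ratio, p, verdict.
#' @export
call_bias <- function(observed, expected_freq, n = sum(observed),
                      p_thresh = 0.01, log2_cutoff = 1.5, p_floor = 1e-10) {
  stopifnot(length(observed) == length(expected_freq))
  if (!is.null(names(observed)) && !is.null(names(expected_freq)))
    expected_freq <- expected_freq[names(observed)]
  if (abs(sum(expected_freq) - 1) > 1e-6)
    stop("expected frequencies must sum to 1")
  x <- as.integer(round(observed))
  y <- as.integer(round(n * expected_freq))
  p <- audic_claverie_p(x, y, n, n)
  corr <- (x == 0L | y == 0L) * 0.5
  lr <- log2((x + corr) / (y + corr))
  lr[x == 0L & y == 0L] <- 0
  verdict <- rep("unbiased", length(x))
  verdict[p < p_thresh & lr >= log2_cutoff] <- "preferred"
  verdict[p < p_thresh & lr <= -log2_cutoff] <- "avoided"
  out <- data.frame(item = if (is.null(names(observed)))
    as.character(seq_along(observed)) else names(observed),
    obs = x, exp = y, log2_ratio = lr, p = pmax(p, p_floor),
    verdict = verdict, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("bias_calls", "data.frame")
  out
}

#' @export
print.bias_calls <- function(x, ...) {
  cat("Bias calls:", nrow(x), "items;",
      sum(x$verdict == "preferred"), "preferred,",
      sum(x$verdict == "avoided"), "avoided\n")
  sig <- x[x$verdict != "unbiased", , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$p), , drop = FALSE]
    print.data.frame(utils::head(sig, 10), row.names = FALSE, digits = 3)
  }
  invisible(x)
}
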