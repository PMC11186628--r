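#' Confusion counts of a matching against ground truth
#'
#' Compares two partial matching matrices cell by cell over the full
#' p1 x p2 grid: a true positive is a cell where both matrices have a 1,
#' and so on.
#'
#' @param m estimated binary matching matrix.
#' @param m_star ground-truth binary matching matrix of the same
#'   dimensions.
#' @return list of class `confusion_counts` with integer `tp`, `fp`, `tn`,
#'   `fn` summing to `p1 * p2`.
#' @export
confusion_counts <- function(m, m_star) {
  m <- validate_matching(m)
  m_star <- validate_matching(m_star)
  if (!all(dim(m) == dim(m_star))) {
    stop("confusion_counts: dimension mismatch")
  }
  tp <- sum(m == 1L & m_star == 1L)
  fp <- sum(m == 1L & m_star == 0L)
  fn <- sum(m == 0L & m_star == 1L)
  tn <- sum(m == 0L & m_star == 0L)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Precision, recall and F1 score
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 their
#' harmonic mean. Empty denominators use total conventions so benchmark
#' loops never fail: with no predicted matches, precision is 1 if there was
#' nothing to find and 0 otherwise; with no true matches, recall is 1; F1
#' is 0 when precision + recall is 0.
#'
#' @param counts a `confusion_counts` (or list with `tp`, `fp`, `fn`).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  precision <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-based confidence interval used to report uncertainty on
#' precision and recall counts. The default is the standard Wilson score
#' interval. `modified = TRUE` applies a boundary adjustment: when the
#' success count is within one of either boundary (0, 1, n-1 or n), the
#' interval limit on that boundary side is replaced by the one-sided exact
#' (Clopper-Pearson) bound at the same nominal level, which widens the
#' interval where the score approximation is weakest.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials, at least 1.
#' @param level confidence level (default 0.95).
#' @param modified apply the boundary adjustment (default FALSE).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' round(wilson_interval(88, 90), 3) # lower 0.923
#' round(wilson_interval(19, 19), 3) # (0.832, 1.000)
#' @export
wilson_interval <- function(successes, n, level = 0.95, modified = FALSE) {
  if (n < 1) stop("wilson_interval: n must be at least 1")
  stopifnot(successes >= 0, successes <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  lower <- max(0, center - half)
  upper <- min(1, center + half)
  if (modified) {
    alpha <- 1 - level
    if (successes <= 1) {
      lower <- if (successes == 0) 0 else {
        stats::qbeta(alpha, successes, n - successes + 1)
      }
    }
    if (successes >= n - 1) {
      upper <- if (successes == n) 1 else {
        stats::qbeta(1 - alpha, successes + 1, n - successes)
      }
    }
  }
  c(lower = lower, upper = upper)
}
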