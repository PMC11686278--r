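# Group-comparison statistics: Holm-Sidak step-down adjustment, paired /
# Welch t-tests, Pearson correlation -- thin, uniformly-shaped wrappers
# over the standard routines plus the step-down adjustment itself.

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the raw p values ascending, applies the Sidak bound
#' \code{1 - (1 - p_(i))^(m - i + 1)} at each step, enforces monotone
#' non-decreasing adjusted values by running maximum, and restores the
#' input order.
#'
#' @param p raw p values in [0, 1].
#' @return Adjusted p values, same order as the input.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 1 - 0.99^2 = 0.0199, then 0.04
#' @export
holm_sidak <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_data("p values must be in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  # guard the p_adjusted >= p_raw contract against 1-ulp rounding in
  # 1 - (1 - p)^k at k = 1
  pmax(out, p)
}

#' Two-sample t test (paired or Welch unpaired)
#'
#' Two-tailed throughout. Unpaired comparisons use Welch's unequal-variance
#' form. Zero-variance paired differences are flagged degenerate rather
#' than returning an infinite statistic.
#'
#' @param x,y numeric samples (equal length when paired).
#' @param paired within-subject comparison.
#' @return List: \code{test}, \code{statistic}, \code{df}, \code{p},
#'   \code{estimate} (mean difference), \code{degenerate}.
#' @export
t_test <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop_data("need n >= 2 per group")
  if (paired) {
    if (length(x) != length(y)) stop_data("paired samples must align")
    d <- x - y
    if (stats::sd(d) == 0) {
      return(list(test = "paired_t", statistic = NA_real_,
                  df = length(d) - 1, p = if (all(d == 0)) 1 else 0,
                  estimate = mean(d), degenerate = TRUE))
    }
  }
  ht <- stats::t.test(x, y, paired = paired, var.equal = FALSE)
  list(test = if (paired) "paired_t" else "welch_t",
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       estimate = if (paired) unname(ht$estimate)
                  else unname(diff(rev(ht$estimate))),
       degenerate = FALSE)
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return List: \code{test}, \code{r}, \code{df}, \code{p}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop_data("need aligned n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("zero variance; correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(test = "pearson", r = unname(ht$estimate),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Adjust a family of comparisons
#'
#' Applies \code{\link{holm_sidak}} within each family of externally or
#' internally computed comparisons and returns a tidy results table.
#'
#' @param results data.frame with at least \code{p_raw} and optionally a
#'   \code{family_id} column (one family if absent).
#' @return The input with a \code{p_adjusted} column.
#' @export
adjust_family <- function(results) {
  fam <- results$family_id %||% rep(1L, nrow(results))
  results$p_adjusted <- stats::ave(results$p_raw, fam, FUN = holm_sidak)
  results
}
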