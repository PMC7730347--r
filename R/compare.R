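# Agreement statistics between two epoch count series: Pearson/Spearman
# correlation, relative difference of totals, Bland-Altman mean difference
# and 1.96-SD limits of agreement, and an ordinary-least-squares regression
# of absolute error on mean intensity.

#' Agreement statistics between two epoch series
#'
#' Compares a comparator series `b` against a reference series `a` of equal
#' length. Bland-Altman differences are `b - a` (comparator minus
#' reference), means are `(a + b) / 2`; the limits of agreement are
#' `mean(d) +/- 1.96 sd(d)`. The error-vs-intensity regression fits
#' `|b - a| ~ (a + b)/2` by ordinary least squares. If either input has zero
#' variance, the correlations are reported as `NA` and
#' `zero_variance = TRUE`.
#'
#' @param a reference epoch series (numeric, length >= 3).
#' @param b comparator epoch series, same length as `a`.
#' @param epoch_s epoch length in seconds of the two series (metadata only;
#'   use [reaggregate()] to move 1-s count series to 10/30/60-s epochs
#'   before comparing).
#' @return An object of class `agreement_report` with fields `pearson_r`,
#'   `spearman_rho` (average ranks for ties), `mean_difference`, `loa_low`,
#'   `loa_high`, `n_outside`, `pct_outside`, `relative_difference_pct`
#'   (`100 (sum(b) - sum(a)) / sum(a)`), `regression_slope`,
#'   `regression_intercept`, `regression_r`, `n`, `epoch_s`,
#'   `zero_variance`, and the `differences`/`means` vectors for plotting.
#' @examples
#' a <- c(10, 20, 30, 40, 50)
#' agreement(a, a + c(1, -1, 2, 0, -2))
#' @export
agreement <- function(a, b, epoch_s = 1) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b))
    stop_invalid("series must have equal length")
  if (length(a) < 3L)
    stop_invalid("need at least 3 points")
  d <- b - a
  m <- (a + b) / 2
  zero_var <- stats::sd(a) == 0 || stats::sd(b) == 0
  pearson <- if (zero_var) NA_real_ else stats::cor(a, b)
  spearman <- if (zero_var) NA_real_ else
    stats::cor(a, b, method = "spearman")
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- md + c(-1.96, 1.96) * sdd
  outside <- d < loa[1] | d > loa[2]
  rel <- if (sum(a) != 0) 100 * (sum(b) - sum(a)) / sum(a) else NA_real_
  if (stats::sd(m) > 0) {
    fit <- stats::lm(abs(d) ~ m)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    reg_r <- if (stats::sd(abs(d)) > 0) stats::cor(m, abs(d)) else NA_real_
  } else {
    slope <- intercept <- reg_r <- NA_real_
  }
  structure(list(pearson_r = pearson, spearman_rho = spearman,
                 mean_difference = md, loa_low = loa[1], loa_high = loa[2],
                 n_outside = sum(outside),
                 pct_outside = 100 * mean(outside),
                 relative_difference_pct = rel,
                 regression_slope = slope, regression_intercept = intercept,
                 regression_r = reg_r, n = length(a), epoch_s = epoch_s,
                 zero_variance = zero_var,
                 differences = d, means = m),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (n =", x$n, ", epoch =", x$epoch_s, "s, sign: comparator - reference)\n")
  cat(sprintf("  Pearson r: %.4f   Spearman rho: %.4f\n",
              x$pearson_r, x$spearman_rho))
  cat(sprintf("  mean difference: %.4g   LoA: [%.4g, %.4g]\n",
              x$mean_difference, x$loa_low, x$loa_high))
  cat(sprintf("  outside LoA: %d (%.2f%%)   relative difference: %.3f%%\n",
              x$n_outside, x$pct_outside, x$relative_difference_pct))
  cat(sprintf("  |error| ~ intensity: slope %.4g, intercept %.4g, r %.3f\n",
              x$regression_slope, x$regression_intercept, x$regression_r))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences (comparator minus reference) against per-pair means, with the
#' mean difference and the 1.96-SD limits of agreement.
#'
#' @param x an [agreement()] report.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of methods (counts)",
                 ylab = "Difference (comparator - reference)",
                 main = "Bland-Altman", pch = 20, col = "#00000080", ...)
  graphics::abline(h = x$mean_difference, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
}

#' Re-aggregate a 1-s count series to longer epochs
#'
#' Sums VM3 counts over consecutive blocks of `epoch_s` seconds; a trailing
#' partial block is dropped. Totals are conserved up to the dropped block.
#'
#' @param counts a [count_series()] at 1-s epochs, or a numeric vector of
#'   1-s VM3 counts.
#' @param epoch_s target epoch length in whole seconds.
#' @return Numeric vector of per-epoch sums.
#' @export
reaggregate <- function(counts, epoch_s) {
  v <- vm3_per_second(counts)
  if (!is_count(epoch_s) || epoch_s < 1)
    stop_invalid("epoch_s must be a whole number of seconds >= 1")
  n_blk <- length(v) %/% epoch_s
  if (n_blk == 0L) return(numeric(0))
  colSums(matrix(v[seq_len(n_blk * epoch_s)], nrow = epoch_s))
}
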