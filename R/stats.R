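# Paired statistical comparisons used for GP-on vs GP-off endpoints.

#' Paired comparison of two per-subject measurement sets
#'
#' Mean +- SD of both sets and of the paired differences, a two-sided paired
#' t-test, and a Wilcoxon signed-rank verification. Degenerate inputs
#' (zero-variance or all-zero differences) are flagged rather than raised.
#'
#' @param x,y numeric vectors of equal length (>= 2), one value per subject.
#' @param alpha significance threshold (default 0.05).
#' @return List of class `paired_comparison`: `n`, `mean_x`, `sd_x`,
#'   `mean_y`, `sd_y`, `mean_diff`, `sd_diff`, `t_p`, `wilcoxon_p`,
#'   `significant` (by the t-test), and `flags`.
#' @export
compare_paired <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 paired observations")
  d <- x - y
  flags <- character(0)
  t_p <- NA_real_; w_p <- NA_real_
  if (stats::sd(d) == 0) {
    flags <- c(flags, "degenerate_t: zero-variance differences")
  } else {
    t_p <- stats::t.test(x, y, paired = TRUE)$p.value
  }
  if (all(d == 0)) {
    flags <- c(flags, "degenerate_wilcoxon: all differences zero")
  } else {
    w_p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value)
  }
  structure(list(n = length(x), mean_x = mean(x), sd_x = stats::sd(x),
                 mean_y = mean(y), sd_y = stats::sd(y),
                 mean_diff = mean(d), sd_diff = stats::sd(d),
                 t_p = t_p, wilcoxon_p = w_p,
                 significant = !is.na(t_p) && t_p < alpha, flags = flags),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> n=%d  x: %.3g+-%.3g  y: %.3g+-%.3g\n",
              x$n, x$mean_x, x$sd_x, x$mean_y, x$sd_y))
  cat(sprintf("  diff: %.3g+-%.3g  paired-t p=%s  wilcoxon p=%s\n",
              x$mean_diff, x$sd_diff, format.pval(x$t_p),
              format.pval(x$wilcoxon_p)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Categorical comparison (chi-square with Fisher verification)
#'
#' @param tab a 2-way contingency table (matrix).
#' @return List with `chisq_p` and `fisher_p`.
#' @export
compare_categorical <- function(tab) {
  tab <- as.matrix(tab)
  chi <- suppressWarnings(stats::chisq.test(tab))
  fis <- stats::fisher.test(tab)
  list(chisq_p = chi$p.value, fisher_p = fis$p.value,
       use_fisher = any(chi$expected < 5))
}
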