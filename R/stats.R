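#' Compare a variable between two synapse groups
#'
#' Reproduces the gated two-sample testing rule: Shapiro-Wilk normality is
#' checked per group and an F test compares variances (both at alpha 0.05);
#' if both groups are compatible with normality and the variances do not
#' differ, an unpaired two-sided t test (equal variances) is used, otherwise
#' the non-parametric Mann-Whitney U (Wilcoxon rank-sum) test.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param variable name of the compared variable (for printing).
#' @param alpha gate level for the normality and variance checks.
#' @return object of class `"group_comparison"` with `test_used`
#'   (`"unpaired_t"` or `"mann_whitney"`), `p_value`, per-group
#'   `normality_p`, `variance_p`, means +/- sem, medians and IQRs.
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(10), rnorm(12, 2))
#' @export
compare_groups <- function(a, b, variable = "value", alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 finite values")
  sw_p <- function(x) {
    if (stats::sd(x) == 0) return(0)           # degenerate: not normal
    stats::shapiro.test(x)$p.value
  }
  norm_a <- sw_p(a); norm_b <- sw_p(b)
  var_p <- if (stats::sd(a) > 0 && stats::sd(b) > 0)
    stats::var.test(a, b)$p.value else 0
  parametric <- norm_a > alpha && norm_b > alpha && var_p > alpha
  p <- if (parametric)
    stats::t.test(a, b, var.equal = TRUE)$p.value
  else
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  summ <- function(x) list(mean = mean(x),
                           sem = stats::sd(x) / sqrt(length(x)),
                           median = stats::median(x),
                           iqr = unname(stats::quantile(x, c(0.25, 0.75))),
                           n = length(x))
  structure(list(variable = variable, group_a = a, group_b = b,
                 test_used = if (parametric) "unpaired_t" else "mann_whitney",
                 p_value = p,
                 normality_p = c(a = norm_a, b = norm_b),
                 variance_p = var_p,
                 summary_a = summ(a), summary_b = summ(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  f <- function(s) sprintf("%.3g +/- %.2g (median %.3g, IQR %.3g-%.3g, n=%d)",
                           s$mean, s$sem, s$median, s$iqr[1], s$iqr[2], s$n)
  cat(sprintf("<group_comparison> %s: %s, p = %.4g\n", x$variable,
              x$test_used, x$p_value))
  cat("  A:", f(x$summary_a), "\n  B:", f(x$summary_b), "\n")
  cat(sprintf("  gates: Shapiro-Wilk p = %.3g / %.3g, F-test p = %.3g\n",
              x$normality_p[1], x$normality_p[2], x$variance_p))
  invisible(x)
}
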