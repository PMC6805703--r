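# Normality-gated statistical routing for grouped metric outputs:
# Welch t-test vs Mann-Whitney U, Pearson vs Spearman.

# Lilliefors-corrected Kolmogorov-Smirnov normality check against a fitted
# normal; n < 5 (too few for the test) routes non-parametric.
ks_normal <- function(x, alpha = 0.05) {
  if (length(x) < 5 || sd(x) == 0) return(FALSE)
  nortest::lillie.test(x)$p.value > alpha
}

#' Compare two groups with normality-gated test selection
#'
#' Routes to Welch's t-test (with Cohen's d) when both groups pass a
#' Kolmogorov-Smirnov (Lilliefors) normality check at `alpha` and both have
#' at least 8 observations; otherwise to the two-sided Mann-Whitney U test
#' (with rank-biserial correlation r = 1 - 2U/(n1*n2)). Group means and
#' SEMs are reported either way.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param alpha level for the normality gate and the significance flag.
#' @return list of class `group_comparison`: `test_name`, `statistic`,
#'   `p_value`, `significant`, `effect_size`, `effect_name`,
#'   `group_summaries` (data.frame of n/mean/sem), `normal` (logical pair),
#'   `rationale`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations", call. = FALSE)
  norm <- c(a = ks_normal(a, alpha), b = ks_normal(b, alpha))
  parametric <- all(norm) && length(a) >= 8 && length(b) >= 8
  if (parametric) {
    tt <- t.test(a, b)                      # Welch
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    res <- list(test_name = "t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value,
                effect_size = (mean(a) - mean(b)) / sp,
                effect_name = "cohens_d",
                rationale = "both groups normal (Lilliefors) and n >= 8")
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = NULL))
    u <- unname(wt$statistic)               # U for the first group
    res <- list(test_name = "mann-whitney", statistic = u,
                p_value = wt$p.value,
                effect_size = 1 - 2 * u / (length(a) * length(b)),
                effect_name = "rank_biserial_r",
                rationale = if (all(norm))
                  "group size below 8: non-parametric routing"
                else "normality rejected (Lilliefors): non-parametric routing")
  }
  res$significant <- res$p_value < alpha
  res$normal <- norm
  res$group_summaries <- data.frame(
    group = c("a", "b"), n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sem = c(sd(a) / sqrt(length(a)), sd(b) / sqrt(length(b))))
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: stat = %.4g, p = %.4g (%s = %.3f)\n",
              x$test_name, x$statistic, x$p_value, x$effect_name,
              x$effect_size))
  cat("  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Correlate two variables with normality-gated method selection
#'
#' Pearson's r is used only when both variables pass the Lilliefors
#' normality check and n > 30 (interval scale is asserted by the caller);
#' otherwise Spearman's rho. Two-sided p-value in both cases.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param alpha level for the normality gate.
#' @return list with `coefficient`, `p_value`, `method` ("pearson" or
#'   "spearman"), `n`, `rationale`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  parametric <- ks_normal(x, alpha) && ks_normal(y, alpha) && length(x) > 30
  method <- if (parametric) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(x),
       rationale = if (parametric) "both variables normal and n > 30"
                   else "normality or n > 30 criterion not met: Spearman")
}
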