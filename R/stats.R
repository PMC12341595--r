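#' F-test-gated two-sample t-test
#'
#' Two-sample comparison as used throughout the pipeline: an F-test for equal
#' variances decides between the pooled-variance and the Welch (unequal
#' variance) t-test. Two-tailed by default; one-tailed variants state the
#' alternative explicitly.
#'
#' When both groups are exactly constant (a zero-noise synthetic scenario) the
#' t statistic is undefined; the p-value is then 1 if the group means are equal
#' and 0 otherwise, and the method is reported as `"degenerate"`.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param variance_test_alpha Level of the gating F-test.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   interpreted as in [stats::t.test()] for `x` relative to `y`.
#' @return A list with `p_value`, `method` (`"pooled"`, `"welch"` or
#'   `"degenerate"`), `f_p_value`, `estimate` (mean difference x - y).
#' @examples
#' compare_to_wt(c(10, 11, 12, 13), c(20, 21, 22, 23))
#' @export
compare_to_wt <- function(x, y, variance_test_alpha = 0.05,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("insufficient replicates: need >= 2 values per group", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    p <- if (d == 0) {
      if (alternative == "two.sided") 1 else 0.5
    } else if (alternative == "two.sided") 0
      else if (alternative == "greater") as.numeric(d < 0)
      else as.numeric(d > 0)
    return(list(p_value = p, method = "degenerate", f_p_value = NA_real_,
                estimate = d))
  }
  f <- stats::var.test(x, y)
  equal_var <- !is.na(f$p.value) && f$p.value >= variance_test_alpha
  tt <- stats::t.test(x, y, alternative = alternative, var.equal = equal_var)
  list(p_value = unname(tt$p.value),
       method = if (equal_var) "pooled" else "welch",
       f_p_value = unname(f$p.value),
       estimate = unname(diff(rev(tt$estimate))))
}
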