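#' Normality-gated test selection
#'
#' The analysis policy uses parametric procedures (Student t, Pearson
#' correlation) for normally distributed data and rank-based procedures
#' (Wilcoxon rank-sum, Spearman correlation) otherwise. The gate is a
#' Shapiro-Wilk test at `alpha = 0.05` on each vector involved; every vector
#' must pass for the parametric branch to be taken. Vectors too short for
#' Shapiro-Wilk (n < 3) or essentially constant fail the gate.
#'
#' @param x numeric vector.
#' @param alpha gate significance level.
#' @return `TRUE` when `x` is consistent with normality at `alpha`.
#' @keywords internal
normality_ok <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) return(FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Two-sample test with normality gating
#'
#' Student t-test (equal variances) when both groups pass the Shapiro-Wilk
#' gate, otherwise Wilcoxon rank-sum with midranks and without continuity
#' correction.
#'
#' @param a,b numeric vectors (non-finite values removed).
#' @param test `"auto"`, `"t"` or `"wilcoxon"`.
#' @return list with elements `test`, `p_value`, `statistic`.
#' @keywords internal
gated_two_sample <- function(a, b, test = c("auto", "t", "wilcoxon")) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (test == "auto") {
    test <- if (normality_ok(a) && normality_ok(b)) "t" else "wilcoxon"
  }
  if (length(unique(c(a, b))) == 1) {
    return(list(test = test, p_value = 1, statistic = NA_real_))
  }
  if (test == "t") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE))
  }
  list(test = test, p_value = unname(ht$p.value),
       statistic = unname(ht$statistic))
}

#' Correlation with normality gating
#'
#' Pearson when both vectors pass the Shapiro-Wilk gate, Spearman otherwise.
#' Constant vectors yield an undefined (NA) coefficient, flagged via
#' `method = "undefined"`.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return list with `r`, `p_value`, `method`, `n`.
#' @keywords internal
gated_correlation <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, method = "undefined", n = n))
  }
  if (method == "auto") {
    method <- if (normality_ok(x) && normality_ok(y)) "pearson" else "spearman"
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p_value = unname(ht$p.value),
       method = method, n = n)
}
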