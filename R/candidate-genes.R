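#' Correlate every gene with a per-sample repertoire metric
#'
#' Computes, for each gene of a log-scale expression matrix, the correlation
#' of its expression with a per-sample metric such as IGHG clonotype
#' abundance or IGHG CPK. With `method = "auto"` the normality-gated policy
#' applies per gene: Pearson when both the gene vector and the metric pass a
#' Shapiro-Wilk gate at 0.05, Spearman otherwise. Constant vectors give an
#' undefined correlation, flagged with `method = "undefined"`.
#'
#' @param expr numeric matrix, genes x samples, column names = sample ids.
#' @param metric named numeric vector of per-sample values; names are
#'   matched against `colnames(expr)` and at least 3 samples must overlap.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return a tibble with columns `gene`, `r`, `p_value`, `method`, `n`.
#' @export
correlate_with_metric <- function(expr, metric,
                                  method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(expr), names(metric))
  if (length(shared) < 3) {
    stop("correlate_with_metric(): fewer than 3 overlapping samples",
         call. = FALSE)
  }
  m <- metric[shared]
  e <- expr[, shared, drop = FALSE]
  res <- lapply(rownames(e), function(g) {
    ct <- gated_correlation(e[g, ], m, method)
    tibble::tibble(gene = g, r = ct$r, p_value = ct$p_value,
                   method = ct$method, n = ct$n)
  })
  dplyr::bind_rows(res)
}

#' Per-gene differential expression with Hochberg adjustment
#'
#' Each gene is compared between the two groups; the default test is the
#' Wilcoxon rank-sum (expression values rarely pass normality), with
#' `test = "auto"` applying the same Shapiro-Wilk gate used everywhere else
#' and `test = "t"` forcing the Student t-test. Raw p-values are adjusted by
#' Hochberg's step-up procedure: with p ordered descending,
#' `p_adj(i) = min(p_adj(i-1), (m - rank + 1) * p(i))`, capped at 1. Genes
#' constant across all samples get p = 1 and are flagged `degenerate`.
#'
#' @param expr numeric matrix, genes x samples.
#' @param groups named character vector, sample id -> group label; exactly
#'   two distinct labels with >= 2 samples each must overlap `expr`.
#' @param test `"wilcoxon"` (default), `"auto"` or `"t"`.
#' @return a tibble with columns `gene`, `p_value`, `p_adj`, `test`,
#'   `degenerate`.
#' @export
differential_expression <- function(expr, groups,
                                    test = c("wilcoxon", "auto", "t")) {
  test <- match.arg(test)
  shared <- intersect(colnames(expr), names(groups))
  g <- groups[shared]
  labs <- unique(g)
  if (length(labs) != 2) {
    stop("differential_expression(): need exactly 2 groups, got ",
         length(labs), call. = FALSE)
  }
  ia <- shared[g == labs[1]]; ib <- shared[g == labs[2]]
  if (length(ia) < 2 || length(ib) < 2) {
    stop("differential_expression(): each group needs >= 2 samples",
         call. = FALSE)
  }
  res <- lapply(rownames(expr), function(gn) {
    a <- expr[gn, ia]; b <- expr[gn, ib]
    degenerate <- length(unique(c(a, b))) == 1
    if (degenerate) {
      tibble::tibble(gene = gn, p_value = 1, test = test, degenerate = TRUE)
    } else {
      ht <- gated_two_sample(a, b,
                             test = if (test == "auto") "auto" else test)
      tibble::tibble(gene = gn, p_value = ht$p_value, test = ht$test,
                     degenerate = FALSE)
    }
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- hochberg_adjust(out$p_value)
  out[, c("gene", "p_value", "p_adj", "test", "degenerate")]
}

#' Hochberg step-up adjustment
#'
#' With the m p-values ordered descending, `p_adj(i) = min(p_adj(i-1),
#' (m - rank + 1) * p(i))`, capped at 1. Adjusted values satisfy
#' `p_adj >= p` and are monotone in the step-up ordering.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
hochberg_adjust <- function(p) {
  stats::p.adjust(p, method = "hochberg")
}

#' Three-criterion candidate-gene selection
#'
#' Reproduces the key-gene discovery procedure: a gene is a candidate when
#' it (1) correlates strongly with IGHG clonotype abundance, (2) correlates
#' strongly with IGHG CPK, and (3) is differentially expressed between
#' groups at Hochberg-adjusted p < `alpha`. By default the correlation
#' criteria use `|r| > r_threshold`: the literal signed rule `r > 0.7` would
#' exclude the procedure's own headline gene, whose CPK correlation is
#' negative (lower CPK indicating stronger clonal expansion). `signed = TRUE`
#' restores the literal rule.
#'
#' @param cor_abundance,cor_cpk tibbles from [correlate_with_metric()]
#'   against IGHG abundance and IGHG CPK.
#' @param de tibble from [differential_expression()].
#' @param r_threshold correlation magnitude threshold (default 0.7).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param signed if `TRUE`, require `r > r_threshold` (signed) instead of
#'   `|r| > r_threshold`.
#' @return a list with `results` (per-gene tibble: `gene`, `r_abundance`,
#'   `r_cpk`, `p_de`, `p_adj`, `pass_abundance`, `pass_cpk`, `pass_de`,
#'   `selected`), `selected` (character vector), and `venn` (named counts of
#'   the seven exclusive regions of the abundance/cpk/de criterion sets,
#'   names like `"abundance&cpk&de"`).
#' @export
select_candidates <- function(cor_abundance, cor_cpk, de,
                              r_threshold = 0.7, alpha = 0.05,
                              signed = FALSE) {
  res <- dplyr::inner_join(
    dplyr::rename(cor_abundance[, c("gene", "r")], r_abundance = "r"),
    dplyr::rename(cor_cpk[, c("gene", "r")], r_cpk = "r"),
    by = "gene")
  res <- dplyr::inner_join(
    res, dplyr::rename(de[, c("gene", "p_value", "p_adj")], p_de = "p_value"),
    by = "gene")
  crit <- function(r) {
    if (signed) !is.na(r) & r > r_threshold else !is.na(r) & abs(r) > r_threshold
  }
  res$pass_abundance <- crit(res$r_abundance)
  res$pass_cpk <- crit(res$r_cpk)
  res$pass_de <- !is.na(res$p_adj) & res$p_adj < alpha
  res$selected <- res$pass_abundance & res$pass_cpk & res$pass_de
  res <- res[order(res$gene), , drop = FALSE]

  a <- res$pass_abundance; b <- res$pass_cpk; d <- res$pass_de
  venn <- c(
    "abundance" = sum(a & !b & !d),
    "cpk" = sum(!a & b & !d),
    "de" = sum(!a & !b & d),
    "abundance&cpk" = sum(a & b & !d),
    "abundance&de" = sum(a & !b & d),
    "cpk&de" = sum(!a & b & d),
    "abundance&cpk&de" = sum(a & b & d))
  list(results = tibble::as_tibble(res), selected = res$gene[res$selected],
       venn = venn)
}
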