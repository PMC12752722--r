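#' Build an IGHV gene usage matrix
#'
#' Read counts of heavy-chain clonotypes are aggregated per allele-trimmed
#' IGHV gene and per sample; alleles of the same gene are merged by
#' summation and genes absent from a sample get 0. A `log2(x + 1)` view is
#' carried alongside the raw counts for display.
#'
#' @param samples a list of [repertoire_sample] objects.
#' @return an object of class `usage_matrix`: a list with `values`
#'   (genes x samples numeric matrix), `log2_values`, and `groups` (named
#'   character vector, sample id -> group label).
#' @export
build_usage <- function(samples) {
  per_sample <- lapply(samples, function(s) {
    cl <- s$clonotypes
    idx <- !is.na(cl$chain_level) & cl$chain_level == "heavy" &
      startsWith(cl$v_call, "IGHV")
    gene <- trim_allele(cl$v_call[idx])
    tapply(cl$read_count[idx], gene, sum)
  })
  genes <- sort(unique(unlist(lapply(per_sample, names))))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  values <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, ids))
  for (j in seq_along(per_sample)) {
    v <- per_sample[[j]]
    if (length(v) > 0) values[names(v), j] <- as.numeric(v)
  }
  groups <- stats::setNames(
    vapply(samples, function(s) s$group, character(1)), ids)
  structure(list(values = values, log2_values = log2(values + 1),
                 groups = groups),
            class = "usage_matrix")
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("<usage_matrix> %d IGHV genes x %d samples (groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Exclude IGHV genes with low expression in a reference group
#'
#' As printed, the exclusion rule drops every gene that is lowly expressed
#' (default: zero abundance) in at least `frac` (default 10%) of the
#' reference group's samples -- an aggressive rule under which a gene
#' missing from 2 of 18 samples is dropped. Because the source method
#' statement is ambiguous, the complementary, more conventional reading
#' ("keep a gene expressed above threshold in at least `frac` of samples")
#' is available via `rule = "keep-if-expressed"`.
#'
#' The operation is idempotent: applying it twice with the same arguments
#' changes nothing.
#'
#' @param usage a `usage_matrix` from [build_usage()].
#' @param group reference group label (e.g. `"TCMR"`).
#' @param frac proportion of the group's samples, in `[0, 1]`.
#' @param low_threshold a gene's value is "low" when `<= low_threshold`
#'   (default 0, i.e. absent).
#' @param rule `"as-printed"` (drop if low in >= frac) or
#'   `"keep-if-expressed"` (keep if expressed in >= frac).
#' @return the filtered `usage_matrix`; attribute `dropped_genes` lists the
#'   removed genes.
#' @export
exclude_low_expression <- function(usage, group, frac = 0.10,
                                   low_threshold = 0,
                                   rule = c("as-printed",
                                            "keep-if-expressed")) {
  rule <- match.arg(rule)
  if (!is.numeric(frac) || frac < 0 || frac > 1) {
    stop("frac must be in [0, 1]", call. = FALSE)
  }
  ids <- names(usage$groups)[usage$groups == group]
  if (length(ids) == 0) stop("group not present: ", group, call. = FALSE)
  sub <- usage$values[, ids, drop = FALSE]
  low_frac <- rowMeans(sub <= low_threshold)
  keep <- if (rule == "as-printed") low_frac < frac else (1 - low_frac) >= frac
  out <- usage
  out$values <- usage$values[keep, , drop = FALSE]
  out$log2_values <- usage$log2_values[keep, , drop = FALSE]
  attr(out, "dropped_genes") <- rownames(usage$values)[!keep]
  out
}

#' Top IGHV genes by group-mean abundance
#'
#' Genes are ranked by their mean abundance over the designated group's
#' samples, descending; ties are broken lexicographically on the gene name
#' so the output is deterministic.
#'
#' @param usage a `usage_matrix`.
#' @param group group label whose mean ranks the genes.
#' @param k number of genes to return; if `k` exceeds the gene count all
#'   genes are returned with a warning.
#' @return character vector of gene names, ranked.
#' @export
top_genes <- function(usage, group, k) {
  ids <- names(usage$groups)[usage$groups == group]
  if (length(ids) == 0) stop("group not present: ", group, call. = FALSE)
  if (nrow(usage$values) == 0) stop("usage matrix has no genes", call. = FALSE)
  means <- rowMeans(usage$values[, ids, drop = FALSE])
  ranked <- names(means)[order(-means, names(means))]
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds gene count ", length(ranked),
            "; returning all genes", call. = FALSE)
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}

#' Intersection of ranked gene lists, preserving first-list order
#'
#' @param ... two or more character vectors of gene names (e.g. top-gene
#'   lists from different datasets).
#' @return the genes present in every list, in the order of the first.
#' @export
intersect_top <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  shared <- Reduce(intersect, lists[-1], init = lists[[1]])
  lists[[1]][lists[[1]] %in% shared]
}
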