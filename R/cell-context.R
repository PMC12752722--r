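#' Partition a single-cell repertoire by annotated cell type
#'
#' Joins clonotype records to a per-barcode cell-type annotation (as
#' produced by upstream clustering/annotation, which this package consumes
#' but never computes). Records whose barcode is absent from the annotation
#' go to an `"unassigned"` bucket with a reported count.
#'
#' @param sample a single-cell [repertoire_sample].
#' @param annotation a data frame with columns `cell_barcode`, `cell_type`
#'   (vocabulary typically includes `"naive B"`, `"memory B"`, `"plasma"`),
#'   and optionally `sample_id` and `group`.
#' @return a named list of [repertoire_sample] objects, one per cell type
#'   present (plus `"unassigned"` when applicable); attribute
#'   `n_unassigned` carries the unassigned cell-record count.
#' @export
join_barcodes <- function(sample, annotation) {
  if (sample$modality != "single_cell") {
    stop("join_barcodes() requires a single-cell sample", call. = FALSE)
  }
  ann <- tibble::as_tibble(annotation)
  if (anyDuplicated(ann$cell_barcode)) {
    stop("annotation barcodes must be unique", call. = FALSE)
  }
  cl <- sample$clonotypes
  idx <- match(cl$cell_barcode, ann$cell_barcode)
  if (all(is.na(idx))) {
    stop("join_barcodes(): no clonotype barcode overlaps the annotation",
         call. = FALSE)
  }
  type <- ifelse(is.na(idx), "unassigned", ann$cell_type[idx])
  parts <- split(seq_len(nrow(cl)), type)
  out <- lapply(parts, function(rows) {
    p <- sample
    p$clonotypes <- cl[rows, , drop = FALSE]
    p
  })
  structure(out, n_unassigned = sum(type == "unassigned"))
}

#' Fold ratio of pooled BCR read abundance between cell types
#'
#' Ratio of summed read counts in cell type `type_a` versus `type_b`,
#' pooled over cells (matching the "absolute abundance" framing; per-cell
#' normalization is available via `per_cell = TRUE`). When
#' `type_b = "B"` and `combine_b = TRUE`, the denominator is the union of
#' naive and memory B cells, the reading under which plasma-versus-B-cell
#' comparisons are usually made.
#'
#' @param partitions named list from [join_barcodes()].
#' @param type_a,type_b cell-type labels.
#' @param combine_b treat `"B"` as naive B + memory B combined.
#' @param per_cell divide each type's reads by its cell count first.
#' @return the fold ratio (a single number); `NA` with a warning when a
#'   cell type is absent or the denominator has zero reads.
#'   `fold(a, b) == 1 / fold(b, a)`.
#' @export
celltype_fold <- function(partitions, type_a = "plasma", type_b = "B",
                          combine_b = TRUE, per_cell = FALSE) {
  pool <- function(type) {
    if (type == "B" && combine_b) {
      types <- intersect(c("naive B", "memory B", "B"), names(partitions))
    } else {
      types <- intersect(type, names(partitions))
    }
    if (length(types) == 0) {
      warning("celltype_fold(): cell type absent: ", type, call. = FALSE)
      return(NA_real_)
    }
    reads <- sum(vapply(partitions[types],
                        function(p) sum(p$clonotypes$read_count), numeric(1)))
    cells <- sum(vapply(partitions[types], function(p) {
      length(unique(p$clonotypes$cell_barcode))
    }, numeric(1)))
    if (per_cell && cells > 0) reads / cells else reads
  }
  num <- pool(type_a)
  den <- pool(type_b)
  if (is.na(num) || is.na(den)) return(NA_real_)
  if (den == 0) {
    warning("celltype_fold(): zero reads in denominator type ", type_b,
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Correlate isotype abundances with immune-infiltration scores
#'
#' For each requested (infiltration cell type, isotype level) pair the
#' per-sample infiltration score is correlated with the per-sample
#' repertoire metric under the normality-gated policy. Scores are consumed
#' as given (absolute-mode deconvolution output); constant score vectors
#' yield an undefined, flagged entry.
#'
#' @param summaries summary tibble from [summarize_cohort()].
#' @param scores data frame with a `sample_id` column and one numeric
#'   column per infiltration cell type.
#' @param cell_types score columns to use (default: all numeric columns).
#' @param levels hierarchy levels to use (default the five isotypes).
#' @param group restrict to one group label, or `NULL` for all samples.
#' @param metric repertoire metric, as in [compare_groups()].
#' @param method correlation method, as in [correlate_with_metric()].
#' @return a tibble with columns `cell_type`, `level`, `r`, `p_value`,
#'   `method`, `n`.
#' @export
correlate_infiltration <- function(summaries, scores, cell_types = NULL,
                                   levels = c("IGHA", "IGHD", "IGHE",
                                              "IGHG", "IGHM"),
                                   group = NULL,
                                   metric = c("clonotypes", "abundance",
                                              "reads", "cpk"),
                                   method = c("auto", "pearson",
                                              "spearman")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  scores <- tibble::as_tibble(scores)
  if (is.null(cell_types)) {
    cell_types <- setdiff(names(scores)[vapply(scores, is.numeric,
                                               logical(1))], "sample_id")
  }
  col <- switch(metric, clonotypes = "n_clonotypes",
                abundance = "n_clonotypes", reads = "n_reads", cpk = "cpk")
  if (!is.null(group)) summaries <- summaries[summaries$group == group, ]
  out <- list()
  for (lv in levels) {
    rows <- summaries[summaries$level == lv, , drop = FALSE]
    m <- stats::setNames(rows[[col]], rows$sample_id)
    shared <- intersect(names(m), scores$sample_id)
    if (length(shared) < 3) {
      stop("correlate_infiltration(): fewer than 3 shared samples",
           call. = FALSE)
    }
    sc <- scores[match(shared, scores$sample_id), , drop = FALSE]
    for (ct in cell_types) {
      ans <- gated_correlation(sc[[ct]], m[shared], method)
      out[[length(out) + 1]] <- tibble::tibble(
        cell_type = ct, level = lv, r = ans$r, p_value = ans$p_value,
        method = ans$method, n = ans$n)
    }
  }
  dplyr::bind_rows(out)
}
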