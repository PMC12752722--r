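#' Summarize a repertoire at every level of the chain hierarchy
#'
#' For each hierarchy level (total, heavy, light, the five heavy-chain
#' isotypes and the IGHG/IGHA subclasses) the summary reports the number of
#' distinct clonotypes (the field's notion of absolute abundance), the
#' summed read count, and the CPK diversity statistic
#' \deqn{CPK = 1000 \times n_{clonotypes} / n_{reads},}
#' computed from that level's records only. CPK is undefined (NA, never 0)
#' when a level has no reads: a zero would masquerade as total clonal
#' collapse. Heavy-chain records with an unresolved constant gene count at
#' the heavy level but at no isotype level, so isotype denominators use only
#' isotype-resolved reads.
#'
#' @param sample a [repertoire_sample].
#' @return a tibble with one row per level: `sample_id`, `group`, `level`,
#'   `n_clonotypes`, `n_reads`, `cpk`.
#' @examples
#' cl <- tibble::tibble(
#'   cdr3_nt = c("TGTGCA", "TGTGCC", "TGTAAA"),
#'   cdr3_aa = c("CA", "CA", "CK"),
#'   v_call = c("IGHV3-23*01", "IGHV1-2*02", "IGKV1-39*01"),
#'   d_call = "", j_call = c("IGHJ4*01", "IGHJ6*01", "IGKJ2*01"),
#'   c_call = c("IGHG1", "IGHG1", "IGKC"), read_count = c(5, 5, 3))
#' s <- repertoire_sample(cl, "S1", "TCMR")
#' summarize_repertoire(s)
#' @export
summarize_repertoire <- function(sample) {
  cl <- sample$clonotypes
  cl <- cl[!is.na(cl$chain_level), , drop = FALSE]
  level_rows <- function(level, idx) {
    n_cl <- sum(idx)
    n_rd <- sum(cl$read_count[idx])
    tibble::tibble(
      sample_id = sample$sample_id, group = sample$group, level = level,
      n_clonotypes = n_cl, n_reads = n_rd,
      cpk = if (n_rd > 0) 1000 * n_cl / n_rd else NA_real_)
  }
  out <- list(level_rows("total", rep(TRUE, nrow(cl))),
              level_rows("heavy", cl$chain_level == "heavy"),
              level_rows("light", cl$chain_level == "light"))
  for (iso in c("IGHA", "IGHD", "IGHE", "IGHG", "IGHM")) {
    out[[length(out) + 1]] <- level_rows(iso, cl$isotype == iso)
  }
  for (sub in c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1", "IGHA2")) {
    out[[length(out) + 1]] <- level_rows(sub, cl$subclass == sub)
  }
  dplyr::bind_rows(out)
}

#' @rdname summarize_repertoire
#' @param samples a list of [repertoire_sample] objects.
#' @return `summarize_cohort()` row-binds the per-sample summaries.
#' @export
summarize_cohort <- function(samples) {
  dplyr::bind_rows(lapply(samples, summarize_repertoire))
}

default_clonality_edges <- c(1, 10, 50, 100)

clonality_bin_labels <- function(edges) {
  lo <- c(0, edges + 1)
  hi <- c(edges, Inf)
  ifelse(is.infinite(hi), paste0(">=", lo), paste0(lo, "-", hi))
}

#' Bin clonotypes into clonality groups by copy number
#'
#' Clonotypes are assigned to copy-count intervals; the default five-group
#' partition is 0-1, 2-10, 11-50, 51-100 and >= 101 copies. The printed
#' description of the original analysis fixes only the outer edges (0-1,
#' 51-100, >= 101); the middle edges default to round decades and are
#' overridable via `edges`.
#'
#' @param samples a list of [repertoire_sample] objects.
#' @param edges increasing positive integers giving the inclusive upper edge
#'   of every bin except the last (which is open-ended); `c(1, 10, 50, 100)`
#'   yields the default five bins.
#' @return a tibble with columns `sample_id`, `group`, `bin`, `n`,
#'   `proportion`. Proportions sum to 1 per non-empty sample; an empty
#'   sample yields `NA` proportions.
#' @export
bin_clonality <- function(samples, edges = default_clonality_edges) {
  if (length(edges) < 1 || any(diff(edges) <= 0) || any(edges < 1) ||
      any(edges != floor(edges))) {
    stop("edges must be increasing positive integers", call. = FALSE)
  }
  labels <- clonality_bin_labels(edges)
  breaks <- c(0, edges, Inf)
  dplyr::bind_rows(lapply(samples, function(s) {
    counts <- s$clonotypes$read_count
    binned <- cut(counts, breaks = breaks, labels = labels,
                  include.lowest = TRUE, right = TRUE)
    n <- as.integer(table(binned))
    tibble::tibble(
      sample_id = s$sample_id, group = s$group,
      bin = factor(labels, levels = labels), n = n,
      proportion = if (length(counts) > 0) n / length(counts) else NA_real_)
  }))
}

#' Compare a repertoire metric between two clinical groups
#'
#' Applies the normality-gated two-sample policy: Student t-test when both
#' groups pass a Shapiro-Wilk gate at 0.05, otherwise Wilcoxon rank-sum
#' (midranks, no continuity correction). Alongside the two-sided p-value the
#' comparison reports the expansion fold as the ratio of group means of the
#' per-sample values, the definition used for fold statements such as the
#' TCMR/STA total-abundance expansion.
#'
#' @param summaries a summary tibble from [summarize_cohort()].
#' @param metric `"clonotypes"` (absolute abundance as a clonotype count;
#'   alias `"abundance"`), `"reads"` (summed read counts) or `"cpk"`.
#' @param level a hierarchy level name (see [bcr_levels()]).
#' @param group_a,group_b group labels; the fold is mean(a)/mean(b).
#' @param test `"auto"` (gated), `"t"` or `"wilcoxon"`.
#' @return a one-row tibble: `metric`, `level`, `group_a`, `group_b`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `fold`, `test`, `p_value`.
#' @export
compare_groups <- function(summaries, metric = c("clonotypes", "abundance",
                                                 "reads", "cpk"),
                           level = "total", group_a, group_b,
                           test = c("auto", "t", "wilcoxon")) {
  metric <- match.arg(metric)
  test <- match.arg(test)
  col <- switch(metric, clonotypes = "n_clonotypes",
                abundance = "n_clonotypes", reads = "n_reads", cpk = "cpk")
  rows <- summaries[summaries$level == level, , drop = FALSE]
  a <- rows[[col]][rows$group == group_a]
  b <- rows[[col]][rows$group == group_b]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("compare_groups(): fewer than 2 usable values in a group ",
         "(", group_a, ": ", length(a), ", ", group_b, ": ", length(b), ")",
         call. = FALSE)
  }
  ht <- gated_two_sample(a, b, test)
  tibble::tibble(
    metric = metric, level = level, group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    fold = mean(a) / mean(b),
    test = ht$test, p_value = ht$p_value)
}

#' Within-parent isotype composition
#'
#' For every hierarchy level with a parent (heavy/light within total,
#' isotypes within heavy, subclasses within IGHG or IGHA) the read-count
#' share of the parent is computed per sample and aggregated per group two
#' ways: pooled (summing reads across the group's samples before dividing)
#' and as the mean of per-sample shares. Both are reported because the two
#' can legitimately differ and published composition figures rarely say
#' which was used.
#'
#' @param summaries a summary tibble from [summarize_cohort()].
#' @return a list with `per_sample` (columns `sample_id`, `group`, `level`,
#'   `parent`, `share`) and `group` (columns `group`, `level`, `parent`,
#'   `pooled_share`, `mean_share`); shares are `NA` where the parent has
#'   zero reads.
#' @export
isotype_proportions <- function(summaries) {
  parents <- bcr_level_parent()
  wide <- summaries |>
    dplyr::select("sample_id", "group", "level", "n_reads") |>
    tidyr::pivot_wider(names_from = "level", values_from = "n_reads")
  per_sample <- dplyr::bind_rows(lapply(names(parents), function(lv) {
    p <- parents[[lv]]
    tibble::tibble(
      sample_id = wide$sample_id, group = wide$group,
      level = lv, parent = p,
      reads = wide[[lv]], parent_reads = wide[[p]],
      share = ifelse(wide[[p]] > 0, wide[[lv]] / wide[[p]], NA_real_))
  }))
  grp <- per_sample |>
    dplyr::group_by(.data$group, .data$level, .data$parent) |>
    dplyr::summarise(
      pooled_share = ifelse(sum(.data$parent_reads) > 0,
                            sum(.data$reads) / sum(.data$parent_reads),
                            NA_real_),
      mean_share = mean(.data$share, na.rm = TRUE),
      .groups = "drop")
  list(per_sample = per_sample[, c("sample_id", "group", "level", "parent",
                                   "share")],
       group = grp)
}
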