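#' Assemble a repertoire sample from clonotype records
#'
#' A `repertoire_sample` holds every assembled receptor chain of one biopsy
#' together with its clinical group label. Clonotype identity is the key
#' `(cdr3_nt, v_call, j_call, c_call)` -- plus `cell_barcode` in single-cell
#' mode -- and duplicate keys are merged by summing `read_count`. The D call
#' is carried but never part of the key (it is frequently absent in
#' short-read assembly).
#'
#' Records with `read_count < 1` or with both `v_call` and `c_call` empty are
#' unclassifiable and rejected; the number rejected is kept in the
#' `n_rejected` attribute.
#'
#' @param clonotypes a data frame with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_call`, `d_call`, `j_call`, `c_call`, `read_count` and optionally
#'   `cell_barcode`. Missing gene calls are the empty string.
#' @param sample_id sample identifier.
#' @param group clinical label (e.g. `"TCMR"`, `"STA"`, `"ACR"`, `"NR"`).
#' @param modality `"bulk"` or `"single_cell"`.
#' @return an object of class `repertoire_sample`: a list with elements
#'   `sample_id`, `group`, `modality` and `clonotypes` (a tibble augmented
#'   with `locus`, `chain_level`, `isotype`, `subclass` columns).
#' @export
repertoire_sample <- function(clonotypes, sample_id, group,
                              modality = c("bulk", "single_cell")) {
  modality <- match.arg(modality)
  cl <- tibble::as_tibble(clonotypes)
  for (col in c("cdr3_nt", "cdr3_aa", "v_call", "d_call", "j_call", "c_call")) {
    if (!col %in% names(cl)) cl[[col]] <- ""
    cl[[col]] <- as.character(cl[[col]])
    cl[[col]][is.na(cl[[col]])] <- ""
  }
  if (!"cell_barcode" %in% names(cl)) cl$cell_barcode <- NA_character_
  cl$read_count <- as.numeric(cl$read_count)

  bad <- is.na(cl$read_count) | cl$read_count < 1 |
    (cl$v_call == "" & cl$c_call == "")
  n_rejected <- sum(bad)
  cl <- cl[!bad, , drop = FALSE]

  key_cols <- c("cdr3_nt", "v_call", "j_call", "c_call")
  if (modality == "single_cell") key_cols <- c(key_cols, "cell_barcode")
  if (nrow(cl) > 0) {
    key <- do.call(paste, c(cl[key_cols], sep = "\r"))
    if (anyDuplicated(key)) {
      cl <- cl |>
        dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
        dplyr::summarise(
          cdr3_aa = dplyr::first(.data$cdr3_aa),
          d_call = dplyr::first(.data$d_call),
          read_count = sum(.data$read_count),
          cell_barcode = dplyr::first(.data$cell_barcode),
          .groups = "drop"
        )
    } else {
      cl <- cl[, c(key_cols, setdiff(c("cdr3_aa", "d_call", "read_count",
                                       "cell_barcode"), key_cols))]
    }
    cls <- classify_chain(cl$v_call, cl$c_call)
    cl <- dplyr::bind_cols(cl, cls)
  } else {
    cl <- tibble::tibble(
      cdr3_nt = character(), v_call = character(), j_call = character(),
      c_call = character(), cdr3_aa = character(), d_call = character(),
      read_count = numeric(), cell_barcode = character(),
      locus = character(), chain_level = character(),
      isotype = character(), subclass = character())
  }
  structure(
    list(sample_id = as.character(sample_id), group = as.character(group),
         modality = modality, clonotypes = cl),
    n_rejected = n_rejected,
    class = "repertoire_sample")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "<repertoire_sample> %s [%s, %s]: %d clonotypes, %d reads\n",
    x$sample_id, x$group, x$modality,
    nrow(x$clonotypes), sum(x$clonotypes$read_count)))
  invisible(x)
}

#' Total read count of a repertoire sample
#' @param sample a [repertoire_sample].
#' @return the summed `read_count` over all clonotypes.
#' @export
total_reads <- function(sample) {
  sum(sample$clonotypes$read_count)
}

airr_col_map <- c(
  cdr3_nt = "junction", cdr3_aa = "junction_aa",
  v_call = "v_call", d_call = "d_call", j_call = "j_call", c_call = "c_call",
  cell_barcode = "cell_id")

#' Read an AIRR Rearrangement TSV into a repertoire sample
#'
#' Consumes the community-standard AIRR Rearrangement schema (as emitted by
#' TRUST4's `--format airr` output, MiXCR export, etc.). The mandatory
#' columns are `junction`, `v_call`, `j_call`, `c_call` and a count column
#' (`duplicate_count`, falling back to `consensus_count`). Rows whose gene
#' calls are all empty, or whose count is missing or non-positive, are
#' counted as rejected and reported via a message, never silently dropped.
#'
#' @param path path to a tab-separated AIRR file.
#' @param sample_id,group sample identifier and clinical group label.
#' @param modality `"bulk"` or `"single_cell"` (single-cell keys clonotypes
#'   by barcode as well).
#' @return a [repertoire_sample]; attribute `n_rejected` carries the number
#'   of rejected rows.
#' @export
read_airr <- function(path, sample_id, group,
                      modality = c("bulk", "single_cell")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  count_col <- if ("duplicate_count" %in% names(raw)) "duplicate_count"
               else "consensus_count"
  mandatory <- c("junction", "v_call", "j_call", "c_call")
  missing_cols <- setdiff(mandatory, names(raw))
  if (!count_col %in% names(raw)) missing_cols <- c(missing_cols, "duplicate_count")
  if (length(missing_cols) > 0) {
    stop("AIRR file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cl <- tibble::tibble(
    cdr3_nt = raw$junction,
    cdr3_aa = if ("junction_aa" %in% names(raw)) raw$junction_aa else "",
    v_call = raw$v_call,
    d_call = if ("d_call" %in% names(raw)) raw$d_call else "",
    j_call = raw$j_call,
    c_call = raw$c_call,
    read_count = suppressWarnings(as.numeric(raw[[count_col]])),
    cell_barcode = if ("cell_id" %in% names(raw)) raw$cell_id else NA_character_)
  out <- repertoire_sample(cl, sample_id, group, modality)
  if (attr(out, "n_rejected") > 0) {
    message(sample_id, ": rejected ", attr(out, "n_rejected"),
            " unclassifiable/invalid row(s)")
  }
  if (nrow(out$clonotypes) == 0) {
    warning("empty repertoire read from ", path, call. = FALSE)
  }
  out
}

#' Write a repertoire sample as an AIRR Rearrangement TSV
#'
#' Column order is fixed and documented: `sequence_id`, `junction`,
#' `junction_aa`, `v_call`, `d_call`, `j_call`, `c_call`,
#' `duplicate_count`, `cell_id`. Reading the file back with [read_airr()]
#' reproduces identical clonotype keys, counts and classifications.
#'
#' @param sample a [repertoire_sample].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(sample, path) {
  cl <- sample$clonotypes
  out <- data.frame(
    sequence_id = sprintf("%s_%06d", sample$sample_id, seq_len(nrow(cl))),
    junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
    v_call = cl$v_call, d_call = cl$d_call, j_call = cl$j_call,
    c_call = cl$c_call, duplicate_count = cl$read_count,
    cell_id = ifelse(is.na(cl$cell_barcode), "", cl$cell_barcode),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TRUST4 report TSV into a repertoire sample
#'
#' TRUST4's `*_report.tsv` dialect: columns `count`, `frequency`, `CDR3nt`,
#' `CDR3aa`, `V`, `D`, `J`, `C` (a leading `#` on the header is tolerated).
#' `*` and `.` placeholders in gene columns map to empty calls. T-cell
#' receptor rows (TRA/TRB/TRG/TRD loci) are discarded and counted in the
#' `n_discarded_tcr` attribute.
#'
#' @inheritParams read_airr
#' @return a [repertoire_sample] with attributes `n_rejected` and
#'   `n_discarded_tcr`.
#' @export
read_trust4_report <- function(path, sample_id, group,
                               modality = c("bulk", "single_cell")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  names(raw) <- sub("^#", "", names(raw))
  needed <- c("count", "CDR3nt", "CDR3aa", "V", "D", "J", "C")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("TRUST4 report ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  counts <- suppressWarnings(as.numeric(raw$count))
  bad_count <- is.na(counts) | counts != floor(counts)
  if (any(bad_count)) {
    stop("TRUST4 report ", path, ": non-integer count field at row(s) ",
         paste(utils::head(which(bad_count), 5), collapse = ", "),
         call. = FALSE)
  }
  clean <- function(x) ifelse(x %in% c("*", "."), "", x)
  v <- clean(raw$V); d <- clean(raw$D); j <- clean(raw$J); cc <- clean(raw$C)
  is_tcr <- grepl("^TR[ABGD]", v) | grepl("^TR[ABGD]", j) | grepl("^TR[ABGD]", cc)
  cl <- tibble::tibble(
    cdr3_nt = raw$CDR3nt[!is_tcr],
    cdr3_aa = raw$CDR3aa[!is_tcr],
    v_call = v[!is_tcr], d_call = d[!is_tcr], j_call = j[!is_tcr],
    c_call = cc[!is_tcr],
    read_count = counts[!is_tcr],
    cell_barcode = if ("barcode" %in% names(raw)) raw$barcode[!is_tcr]
                   else NA_character_)
  out <- repertoire_sample(cl, sample_id, group, modality)
  attr(out, "n_discarded_tcr") <- sum(is_tcr)
  if (nrow(out$clonotypes) == 0) {
    warning("empty repertoire read from ", path, call. = FALSE)
  }
  out
}

#' Keep only complete, productive clonotypes
#'
#' Retains records with a non-empty CDR3 nucleotide sequence whose amino-acid
#' CDR3 contains no out-of-frame marker (`_`, TRUST4's convention), no stop
#' codon (`*`) and no partial-sequence marker (`?` or `.`). The per-reason
#' discard tally is attached as the `discard_tally` attribute. Group-level
#' antibody-class statistics implicitly assume productive chains, but the
#' filter can be skipped by not calling it (readers never apply it
#' implicitly).
#'
#' @param sample a [repertoire_sample].
#' @return a new [repertoire_sample] containing only complete records, with
#'   attribute `discard_tally` (named integer vector with entries `no_cdr3`,
#'   `out_of_frame`, `stop_codon`, `partial`).
#' @export
filter_complete <- function(sample) {
  cl <- sample$clonotypes
  no_cdr3 <- cl$cdr3_nt == ""
  oof <- !no_cdr3 & grepl("_", cl$cdr3_aa, fixed = TRUE)
  stopc <- !no_cdr3 & !oof & grepl("*", cl$cdr3_aa, fixed = TRUE)
  partial <- !no_cdr3 & !oof & !stopc & grepl("[?.]", cl$cdr3_aa)
  keep <- !(no_cdr3 | oof | stopc | partial)
  tally <- c(no_cdr3 = sum(no_cdr3), out_of_frame = sum(oof),
             stop_codon = sum(stopc), partial = sum(partial))
  out <- sample
  out$clonotypes <- cl[keep, , drop = FALSE]
  attr(out, "n_rejected") <- attr(sample, "n_rejected")
  attr(out, "discard_tally") <- tally[tally > 0]
  out
}
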