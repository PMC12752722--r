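#' Immunoglobulin chain hierarchy
#'
#' The analysis views every assembled receptor chain through a fixed
#' hierarchy: total -> heavy/light -> isotype (IGHA, IGHD, IGHE, IGHG, IGHM)
#' -> subclass (IGHG1-4, IGHA1-2). Light chains (IGK, IGL) carry no isotype.
#'
#' @return `bcr_levels()` returns the character vector of hierarchy level
#'   names in canonical order; `bcr_level_parent()` returns the named parent
#'   of each non-total level.
#' @export
bcr_levels <- function() {
  c("total", "heavy", "light",
    "IGHA", "IGHD", "IGHE", "IGHG", "IGHM",
    "IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1", "IGHA2")
}

#' @rdname bcr_levels
#' @export
bcr_level_parent <- function() {
  c(heavy = "total", light = "total",
    IGHA = "heavy", IGHD = "heavy", IGHE = "heavy",
    IGHG = "heavy", IGHM = "heavy",
    IGHG1 = "IGHG", IGHG2 = "IGHG", IGHG3 = "IGHG", IGHG4 = "IGHG",
    IGHA1 = "IGHA", IGHA2 = "IGHA")
}

#' Trim IMGT allele suffixes from gene names
#'
#' `"IGHV3-23*01"` becomes `"IGHV3-23"`. All gene-name comparisons in the
#' package happen at gene, not allele, resolution.
#'
#' @param x character vector of gene calls (may contain `NA` or `""`).
#' @return character vector with everything from the first `*` removed.
#' @export
trim_allele <- function(x) {
  sub("\\*.*$", "", x)
}

#' Classify receptor chains into locus, chain level, isotype and subclass
#'
#' Locus is taken from the constant-region call when present, otherwise from
#' the V call (IGH -> heavy; IGK/IGL -> light). The isotype is resolved from
#' the allele-trimmed constant call (IGHA/IGHD/IGHE/IGHG/IGHM prefix); the
#' subclass only for IGHG1-IGHG4 and IGHA1-IGHA2. A heavy chain whose
#' constant gene is missing or unresolvable keeps isotype `"none"`: it still
#' counts at the heavy-chain level but never enters isotype denominators.
#'
#' @param v_call,c_call character vectors (recycled to common length) of V
#'   and constant gene calls; empty string or `NA` means missing.
#' @return a [tibble::tibble] with columns `locus` (IGH/IGK/IGL/NA),
#'   `chain_level` (heavy/light/NA), `isotype` and `subclass` (`"none"` when
#'   unresolved).
#' @examples
#' classify_chain("IGHV1-2*02", "IGHG3")
#' classify_chain("IGKV1-39*01", "IGKC")
#' @export
classify_chain <- function(v_call, c_call) {
  n <- max(length(v_call), length(c_call))
  v <- rep_len(as.character(v_call), n)
  cc <- rep_len(as.character(c_call), n)
  v[is.na(v)] <- ""
  cc[is.na(cc)] <- ""
  if (any(v == "" & cc == "")) {
    stop("classify_chain(): both v_call and c_call empty for ",
         sum(v == "" & cc == ""), " record(s)", call. = FALSE)
  }
  v <- trim_allele(v)
  cc <- trim_allele(cc)

  src <- ifelse(cc != "", cc, v)
  locus <- substr(src, 1L, 3L)
  locus[!locus %in% c("IGH", "IGK", "IGL")] <- NA_character_
  chain_level <- ifelse(is.na(locus), NA_character_,
                        ifelse(locus == "IGH", "heavy", "light"))

  iso4 <- substr(cc, 1L, 4L)
  isotype <- ifelse(!is.na(chain_level) & chain_level == "heavy" & cc != "" &
                      iso4 %in% c("IGHA", "IGHD", "IGHE", "IGHG", "IGHM"),
                    iso4, "none")
  subclass <- ifelse(isotype %in% c("IGHG", "IGHA") &
                       cc %in% c("IGHG1", "IGHG2", "IGHG3", "IGHG4",
                                 "IGHA1", "IGHA2"),
                     cc, "none")
  tibble::tibble(locus = locus, chain_level = chain_level,
                 isotype = isotype, subclass = subclass)
}
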