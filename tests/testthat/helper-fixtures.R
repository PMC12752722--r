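# In-code fixture builders shared across test files.

# Quick clonotype table: one row per element of `counts`; gene calls are
# recycled. CDR3s are made unique unless explicitly supplied.
make_clonotypes <- function(counts, c_call = "IGHG1", v_call = "IGHV3-23*01",
                            j_call = "IGHJ4*01", cdr3_nt = NULL,
                            cdr3_aa = NULL, cell_barcode = NULL) {
  n <- length(counts)
  if (is.null(cdr3_nt)) {
    cdr3_nt <- sprintf("TGTGC%sTGG", strrep("A", seq_len(n)))
  }
  if (is.null(cdr3_aa)) cdr3_aa <- rep("CARW", n)
  tibble::tibble(
    cdr3_nt = rep_len(cdr3_nt, n), cdr3_aa = rep_len(cdr3_aa, n),
    v_call = rep_len(v_call, n), d_call = "",
    j_call = rep_len(j_call, n), c_call = rep_len(c_call, n),
    read_count = counts,
    cell_barcode = if (is.null(cell_barcode)) NA_character_
                   else rep_len(cell_barcode, n))
}

make_sample <- function(counts, c_call = "IGHG1", sample_id = "S1",
                        group = "TCMR", modality = "bulk", ...) {
  repertoire_sample(make_clonotypes(counts, c_call = c_call, ...),
                    sample_id, group, modality)
}

# Small-cohort config for mechanics tests (study-shape defaults are
# exercised in test-acceptance.R).
small_config <- function(n_tcmr = 4, n_sta = 4, clonotypes_sta = 40, ...) {
  synthetic_config(seed = 42, n_tcmr = n_tcmr, n_sta = n_sta,
                   clonotypes_sta = clonotypes_sta, ...)
}

write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Brute-force Hochberg step-up, straight from the definition.
hochberg_brute <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  prev <- Inf
  for (i in seq_len(m)) {
    rank_asc <- m - i + 1
    val <- min(prev, (m - rank_asc + 1) * p[ord[i]], 1)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# permutation distribution of the Mann-Whitney U statistic (tie-free data).
wilcox_exact_brute <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  combos <- utils::combn(n1 + n2, n1)
  w_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (w_obs > mu) {
    p <- 2 * mean(w_all >= w_obs)
  } else if (w_obs < mu) {
    p <- 2 * mean(w_all <= w_obs)
  } else {
    p <- 1
  }
  min(p, 1)
}
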