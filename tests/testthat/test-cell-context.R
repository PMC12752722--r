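sc_toy <- function() {
  # 5 one-clonotype cells: 3 plasma, 2 naive B; known read totals
  cl <- make_clonotypes(c(100, 200, 300, 4, 6),
                        cell_barcode = sprintf("BC%d", 1:5),
                        cdr3_nt = sprintf("TGT%sTGG",
                                          c("AAA", "CCC", "GGG", "TTT",
                                            "ACA")))
  s <- repertoire_sample(cl, "SC1", "ACR", "single_cell")
  ann <- tibble::tibble(
    cell_barcode = sprintf("BC%d", 1:5),
    cell_type = c("plasma", "plasma", "plasma", "naive B", "naive B"),
    sample_id = "SC1", group = "ACR")
  list(sample = s, annotation = ann)
}

test_that("join_barcodes partitions by cell type and buckets unassigned", {
  toy <- sc_toy()
  parts <- join_barcodes(toy$sample, toy$annotation)
  expect_equal(nrow(parts$plasma$clonotypes), 3)
  expect_equal(nrow(parts$"naive B"$clonotypes), 2)
  expect_equal(attr(parts, "n_unassigned"), 0)
  # per-type read totals match hand sums
  expect_equal(sum(parts$plasma$clonotypes$read_count), 600)
  expect_equal(sum(parts$"naive B"$clonotypes$read_count), 10)
  # partition sizes sum to total records
  expect_equal(sum(vapply(parts, function(p) nrow(p$clonotypes),
                          numeric(1))),
               nrow(toy$sample$clonotypes))

  ann_missing <- toy$annotation[-1, ]
  parts2 <- join_barcodes(toy$sample, ann_missing)
  expect_equal(attr(parts2, "n_unassigned"), 1)
  expect_equal(nrow(parts2$unassigned$clonotypes), 1)

  ann_none <- toy$annotation
  ann_none$cell_barcode <- paste0("ZZ", 1:5)
  expect_error(join_barcodes(toy$sample, ann_none), "no clonotype barcode")
  bulk <- make_sample(5)
  expect_error(join_barcodes(bulk, toy$annotation), "single-cell")
})

test_that("celltype_fold is a pooled read ratio with documented edge cases", {
  toy <- sc_toy()
  parts <- join_barcodes(toy$sample, toy$annotation)
  expect_equal(celltype_fold(parts, "plasma", "B"), 60)
  expect_equal(celltype_fold(parts, "plasma", "naive B"), 60)
  # symmetry: fold(a, b) = 1 / fold(b, a)
  expect_equal(celltype_fold(parts, "naive B", "plasma"),
               1 / celltype_fold(parts, "plasma", "naive B"))
  # scale equivariance: common read scaling cancels
  scaled <- parts
  for (nm in names(scaled)) {
    scaled[[nm]]$clonotypes$read_count <-
      scaled[[nm]]$clonotypes$read_count * 7
  }
  expect_equal(celltype_fold(scaled, "plasma", "B"),
               celltype_fold(parts, "plasma", "B"))
  # absent cell type is flagged undefined, not an error
  expect_warning(f <- celltype_fold(parts, "plasma", "memory B"), "absent")
  expect_true(is.na(f))
})

test_that("a 182:1 read-ratio toy reproduces the fold exactly", {
  cl <- make_clonotypes(c(1820, 10),
                        cell_barcode = c("P1", "B1"),
                        cdr3_nt = c("TGTAAATGG", "TGTCCCTGG"))
  s <- repertoire_sample(cl, "SC1", "ACR", "single_cell")
  ann <- tibble::tibble(cell_barcode = c("P1", "B1"),
                        cell_type = c("plasma", "naive B"),
                        sample_id = "SC1", group = "ACR")
  expect_equal(celltype_fold(join_barcodes(s, ann)), 182)
})

test_that("zero plasma cells flags the fold undefined", {
  cfg <- small_config(single_cell = list(n_naive = 30, n_memory = 20,
                                         n_plasma = 0))
  sc <- generate_single_cell(cfg)
  parts <- join_barcodes(sc$sample, sc$annotation)
  expect_warning(f <- celltype_fold(parts), "absent")
  expect_true(is.na(f))
})

test_that("correlate_infiltration matches scores against repertoire metrics", {
  cfg <- small_config(n_tcmr = 9, n_sta = 9)
  sm <- summarize_cohort(generate_repertoire_cohort(cfg)$samples)
  ighg <- sm[sm$level == "IGHG", ]
  scores <- tibble::tibble(sample_id = ighg$sample_id,
                           "Plasma cells" = ighg$n_clonotypes,
                           "NK cells" = 3)
  res <- correlate_infiltration(sm, scores, levels = "IGHG")
  expect_equal(res$r[res$cell_type == "Plasma cells"], 1)
  expect_equal(res$method[res$cell_type == "NK cells"], "undefined")
  expect_true(is.na(res$r[res$cell_type == "NK cells"]))
})

test_that("an implanted plasma-score correlation of 0.8 is recovered", {
  cfg <- synthetic_config(seed = 21)
  sm <- summarize_cohort(generate_repertoire_cohort(cfg)$samples)
  infil <- generate_infiltration(cfg, sm)
  res <- correlate_infiltration(sm, infil$scores,
                                cell_types = "Plasma cells",
                                levels = "IGHG", method = "pearson")
  expect_lt(abs(res$r - 0.8), 0.1)
})

test_that("independent scores give small correlations, p near permutation oracle", {
  cfg <- small_config(n_tcmr = 9, n_sta = 9)
  sm <- summarize_cohort(generate_repertoire_cohort(cfg)$samples)
  ighg <- sm[sm$level == "IGHG", ]
  set.seed(77)
  scores <- tibble::tibble(sample_id = ighg$sample_id,
                           "NK cells" = rnorm(nrow(ighg)))
  res <- correlate_infiltration(sm, scores, levels = "IGHG",
                                method = "spearman")
  # permutation oracle for the Spearman p-value
  x <- scores$"NK cells"
  y <- ighg$n_clonotypes
  r_obs <- cor(x, y, method = "spearman")
  set.seed(78)
  r_null <- replicate(4000, cor(x, sample(y), method = "spearman"))
  p_perm <- mean(abs(r_null) >= abs(r_obs) - 1e-12)
  expect_lt(abs(res$p_value - p_perm), 0.02)
})
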