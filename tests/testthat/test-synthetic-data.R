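test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(total_abundance_fold = -1), "folds")
  bad_mix <- c(IGHG1 = 0.8, IGK = 0.1)
  expect_error(synthetic_config(isotype_mixture_tcmr = bad_mix),
               "probability vector")
  expect_error(
    synthetic_config(expression = list(
      implants = data.frame(gene = "g", r_abundance = 1, r_cpk = 0.2,
                            de_shift = 0))),
    "\\(-1, 1\\)")
  expect_error(synthetic_config(survival = list(censoring = 1)),
               "censoring")
  # IGHG1 fold below the total fold would need an STA probability > TCMR's;
  # an extreme setting pushes it out of (0, 1)
  expect_error(synthetic_config(ighg1_fold = 0.01), "IGHG1")
})

test_that("the derived STA mixture encodes the IGHG1 fold exactly", {
  cfg <- synthetic_config()
  expect_equal(sum(cfg$isotype_mixture_sta), 1)
  expect_equal(
    unname(cfg$isotype_mixture_tcmr["IGHG1"] /
             cfg$isotype_mixture_sta["IGHG1"] * cfg$total_abundance_fold),
    cfg$ighg1_fold)
})

test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- small_config()
  a <- generate_repertoire_cohort(cfg, seed = 99)
  b <- generate_repertoire_cohort(cfg, seed = 99)
  expect_identical(a, b)
  p1 <- tempfile(); p2 <- tempfile()
  write_airr(a$samples[[1]], p1)
  write_airr(b$samples[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))

  sc1 <- generate_single_cell(cfg, seed = 5)
  sc2 <- generate_single_cell(cfg, seed = 5)
  expect_identical(sc1, sc2)
})

test_that("a null expansion fold gives equal group totals on average", {
  cfg <- small_config(total_abundance_fold = 1, clonotype_fold = 1,
                      ighg1_fold = 1)
  folds <- vapply(1:10, function(s) {
    sm <- summarize_cohort(generate_repertoire_cohort(cfg, seed = s)$samples)
    tot <- sm[sm$level == "total", ]
    mean(tot$n_reads[tot$group == "TCMR"]) /
      mean(tot$n_reads[tot$group == "STA"])
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.25)
})

test_that("ground truth is emitted alongside every generated object", {
  cfg <- small_config()
  coh <- generate_repertoire_cohort(cfg)
  expect_equal(coh$truth$total_abundance_fold, cfg$total_abundance_fold)
  sc <- generate_single_cell(cfg)
  expect_equal(sc$truth$read_ratio, cfg$single_cell$read_ratio)
  sm <- summarize_cohort(coh$samples)
  ex <- generate_expression(cfg, sm)
  expect_named(ex$truth$implants, cfg$expression$implants$gene)
  sv <- generate_survival(cfg)
  expect_equal(sv$truth$hr, cfg$survival$hr)
})

test_that("expression implants hit their target correlations exactly in-sample", {
  cfg <- small_config(n_tcmr = 17, n_sta = 17)
  sm <- summarize_cohort(generate_repertoire_cohort(cfg)$samples)
  ex <- generate_expression(cfg, sm)
  g <- ex$expr["implant_1", ]
  expect_equal(cor(g, ex$metrics$abundance[names(g)]), 0.891)
  expect_equal(cor(g, ex$metrics$cpk[names(g)]), -0.703)
})

test_that("infeasible joint correlation targets are rejected", {
  cfg <- small_config(
    n_tcmr = 17, n_sta = 17,
    expression = list(implants = data.frame(
      gene = "g", r_abundance = 0.95, r_cpk = 0.95, de_shift = 0)))
  sm <- summarize_cohort(generate_repertoire_cohort(cfg)$samples)
  # abundance and CPK are strongly negatively correlated across groups, so
  # demanding strong positive correlation with both is impossible
  expect_error(generate_expression(cfg, sm), "infeasible")
})

test_that("single-cell generator respects configured cell counts and barcodes", {
  cfg <- small_config(single_cell = list(n_naive = 40, n_memory = 25,
                                         n_plasma = 6, read_ratio = 20))
  sc <- generate_single_cell(cfg)
  expect_equal(as.vector(table(sc$annotation$cell_type)[
    c("naive B", "memory B", "plasma")]), c(40, 25, 6))
  expect_true(all(sc$sample$clonotypes$cell_barcode %in%
                    sc$annotation$cell_barcode))
  parts <- join_barcodes(sc$sample, sc$annotation)
  expect_equal(attr(parts, "n_unassigned"), 0)
})

test_that("zero censoring observes every event", {
  cfg <- small_config(survival = list(censoring = 0, n = 60))
  sv <- generate_survival(cfg)
  expect_true(all(sv$records$event == 1))
  cfg40 <- small_config(survival = list(censoring = 0.4, n = 400))
  sv40 <- generate_survival(cfg40)
  expect_lt(abs(mean(sv40$records$event) - 0.6), 0.12)
})

test_that("simulate_cohort writes a complete, re-readable fixture", {
  cfg <- small_config(expression = list(n_genes = 20),
                      single_cell = list(n_naive = 30, n_memory = 20,
                                         n_plasma = 5, read_ratio = 30),
                      survival = list(n = 50))
  dir <- file.path(tempdir(), "fixture")
  simulate_cohort(cfg, dir)
  sheet <- utils::read.delim(file.path(dir, "sample_sheet.tsv"))
  expect_equal(nrow(sheet), cfg$n_tcmr + cfg$n_sta)
  s1 <- read_airr(file.path(dir, paste0(sheet$sample_id[1], ".airr.tsv")),
                  sheet$sample_id[1], sheet$group[1])
  expect_gt(nrow(s1$clonotypes), 0)
  expr <- utils::read.delim(file.path(dir, "expression.tsv"),
                            check.names = FALSE)
  expect_equal(nrow(expr), 21)  # 20 null genes + 1 implant
  expect_true(file.exists(file.path(dir, "sc_annotation.tsv")))
  expect_true(file.exists(file.path(dir, "infiltration.tsv")))
  expect_true(file.exists(file.path(dir, "survival.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$repertoire$total_abundance_fold,
               cfg$total_abundance_fold)
  unlink(dir, recursive = TRUE)
})
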