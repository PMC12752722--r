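test_that("summarize_repertoire computes counts, reads and CPK per level", {
  s <- make_sample(rep(100, 10), c_call = "IGHG1")
  sm <- summarize_repertoire(s)
  for (lv in c("total", "heavy", "IGHG", "IGHG1")) {
    row <- sm[sm$level == lv, ]
    expect_equal(row$n_clonotypes, 10)
    expect_equal(row$n_reads, 1000)
    expect_equal(row$cpk, 10)
  }
  expect_equal(sm$n_reads[sm$level == "light"], 0)
  expect_true(is.na(sm$cpk[sm$level == "light"]))

  one <- make_sample(1000)
  expect_equal(summarize_repertoire(one)$cpk[1], 1)
})

test_that("mixed heavy/light sample matches hand-computed level stats", {
  cl <- dplyr::bind_rows(
    make_clonotypes(c(5, 5), c_call = "IGHG1",
                    cdr3_nt = c("TGTAAATGG", "TGTCCCTGG")),
    make_clonotypes(c(1, 1, 1), c_call = "IGKC", v_call = "IGKV1-39*01",
                    j_call = "IGKJ2*01",
                    cdr3_nt = c("TGTAAGTGG", "TGTCCGTGG", "TGTGGGTGG")))
  sm <- summarize_repertoire(repertoire_sample(cl, "S1", "TCMR"))
  expect_equal(unlist(sm[sm$level == "heavy",
                         c("n_clonotypes", "n_reads", "cpk")],
                      use.names = FALSE), c(2, 10, 200))
  expect_equal(unlist(sm[sm$level == "light",
                         c("n_clonotypes", "n_reads", "cpk")],
                      use.names = FALSE), c(3, 3, 1000))
  expect_equal(unlist(sm[sm$level == "total",
                         c("n_clonotypes", "n_reads", "cpk")],
                      use.names = FALSE), c(5, 13, 1000 * 5 / 13))
})

test_that("hierarchy levels are consistent: total = heavy + light, parents >= children", {
  cfg <- small_config()
  for (s in generate_repertoire_cohort(cfg)$samples[1:4]) {
    sm <- summarize_repertoire(s)
    v <- function(lv, col) sm[[col]][sm$level == lv]
    expect_equal(v("total", "n_clonotypes"),
                 v("heavy", "n_clonotypes") + v("light", "n_clonotypes"))
    isotypes <- c("IGHA", "IGHD", "IGHE", "IGHG", "IGHM")
    expect_gte(v("heavy", "n_reads"),
               sum(vapply(isotypes, v, numeric(1), col = "n_reads")))
    expect_gte(v("IGHG", "n_reads"),
               sum(vapply(paste0("IGHG", 1:4), v, numeric(1),
                          col = "n_reads")))
  }
})

test_that("bin_clonality assigns copy counts to the five default bins", {
  s <- make_sample(c(1, 1, 60, 200))
  b <- bin_clonality(list(s))
  expect_equal(as.character(b$bin), c("0-1", "2-10", "11-50", "51-100",
                                      ">=101"))
  expect_equal(b$n, c(2L, 0L, 0L, 1L, 1L))
  expect_equal(b$proportion, c(0.5, 0, 0, 0.25, 0.25))

  ones <- make_sample(rep(1, 7))
  b1 <- bin_clonality(list(ones))
  expect_equal(b1$proportion[1], 1)
  expect_equal(sum(b1$proportion), 1)

  empty <- repertoire_sample(make_clonotypes(numeric(0)), "E", "STA")
  expect_true(all(is.na(bin_clonality(list(empty))$proportion)))

  expect_error(bin_clonality(list(s), edges = c(10, 5)), "increasing")
})

test_that("compare_groups reports fold and a normality-gated p-value", {
  mk <- function(vals, group, prefix) {
    lapply(seq_along(vals), function(i) {
      make_sample(rep(1, vals[i]), sample_id = paste0(prefix, i),
                  group = group)
    })
  }
  # identical multisets: fold 1, p 1 under the rank test
  sams <- c(mk(c(5, 8, 11), "TCMR", "T"), mk(c(5, 8, 11), "STA", "S"))
  cmp <- compare_groups(summarize_cohort(sams), "clonotypes", "total",
                        "TCMR", "STA", test = "wilcoxon")
  expect_equal(cmp$fold, 1)
  expect_equal(cmp$p_value, 1)

  # element-wise 10x scaling: fold 10
  sams2 <- c(mk(c(50, 80, 110, 60, 90), "TCMR", "T"),
             mk(c(5, 8, 11, 6, 9), "STA", "S"))
  cmp2 <- compare_groups(summarize_cohort(sams2), "clonotypes", "total",
                         "TCMR", "STA")
  expect_equal(cmp2$fold, 10)

  expect_error(
    compare_groups(summarize_cohort(sams[c(1, 4, 5)]), "clonotypes",
                   "total", "TCMR", "STA"),
    "fewer than 2")
})

test_that("well-separated groups give an extreme rank-test p-value", {
  set.seed(11)
  a <- rnorm(20)
  b <- a + 10
  sm <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("A", 1:20), group = "A",
                   level = "total", n_clonotypes = 1, n_reads = 1, cpk = a),
    tibble::tibble(sample_id = paste0("B", 1:20), group = "B",
                   level = "total", n_clonotypes = 1, n_reads = 1, cpk = b))
  cmp <- compare_groups(sm, "cpk", "total", "A", "B", test = "wilcoxon")
  expect_lt(cmp$p_value, 1e-6)
})

test_that("isotype_proportions gives within-parent shares, pooled and per-sample", {
  s <- make_sample(c(10, 5), c_call = "IGHG1")
  ip <- isotype_proportions(summarize_repertoire(s))
  ps <- ip$per_sample
  expect_equal(ps$share[ps$level == "IGHG1"], 1)

  cl <- dplyr::bind_rows(
    make_clonotypes(c(919), c_call = "IGHG1", cdr3_nt = "TGTAAATGG"),
    make_clonotypes(c(50), c_call = "IGHG2", cdr3_nt = "TGTCCCTGG"),
    make_clonotypes(c(21), c_call = "IGHG3", cdr3_nt = "TGTGGGTGG"),
    make_clonotypes(c(10), c_call = "IGHG4", cdr3_nt = "TGTTTTTGG"))
  ip2 <- isotype_proportions(
    summarize_repertoire(repertoire_sample(cl, "S1", "TCMR")))
  expect_equal(
    ip2$per_sample$share[ip2$per_sample$level == "IGHG1"], 0.919)

  # pooled vs mean share: equal parent reads, shares 0.8 and 1.0
  mk2 <- function(g1, g2, id) {
    cl <- dplyr::bind_rows(
      make_clonotypes(g1, c_call = "IGHG1", cdr3_nt = "TGTAAATGG"),
      if (g2 > 0) make_clonotypes(g2, c_call = "IGHG2",
                                  cdr3_nt = "TGTCCCTGG"))
    repertoire_sample(cl, id, "TCMR")
  }
  ip3 <- isotype_proportions(
    summarize_cohort(list(mk2(80, 20, "A"), mk2(100, 0, "B"))))
  g <- ip3$group
  expect_equal(g$pooled_share[g$level == "IGHG1"], 0.9)
  expect_equal(g$mean_share[g$level == "IGHG1"], 0.9)
})

test_that("CPK never exceeds 1000 and summarize is merge-invariant", {
  cfg <- small_config()
  samples <- generate_repertoire_cohort(cfg)$samples
  for (s in samples) {
    sm <- summarize_repertoire(s)
    expect_true(all(sm$cpk[!is.na(sm$cpk)] <= 1000 + 1e-9))
  }
  # splitting a record into two rows with the same key changes nothing
  s <- samples[[1]]
  cl <- s$clonotypes[, c("cdr3_nt", "cdr3_aa", "v_call", "d_call",
                         "j_call", "c_call", "read_count")]
  big <- cl$read_count >= 2
  split1 <- cl[big, ]; split1$read_count <- floor(split1$read_count / 2)
  split2 <- cl[big, ]
  split2$read_count <- split2$read_count - floor(split2$read_count / 2)
  resplit <- dplyr::bind_rows(cl[!big, ], split1, split2)
  s2 <- repertoire_sample(resplit, s$sample_id, s$group)
  sm1 <- summarize_repertoire(s)
  sm2 <- summarize_repertoire(s2)
  expect_equal(sm2, sm1)
  # CPK = 1000 exactly when every clonotype is a singleton
  singletons <- make_sample(rep(1, 25))
  expect_equal(summarize_repertoire(singletons)$cpk[1], 1000)
})
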