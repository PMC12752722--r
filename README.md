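# graftBCR

B-cell receptor (BCR) repertoire analytics for kidney transplant biopsies.

Rejecting allografts — in particular biopsies with T cell-mediated
rejection (TCMR) — carry massively expanded, IgG1-dominated BCR
repertoires compared with stable grafts (STA). `graftBCR` implements the
downstream analysis of such repertoires once chains have been assembled
from RNA-seq (e.g. by TRUST4): it is aimed at transplant immunologists and
computational biologists who want the full pipeline from clonotype tables
to survival stratification as tested, reusable functions.

## What it computes

* **Clonotype I/O** — readers for AIRR Rearrangement TSV and TRUST4 report
  TSV; clonotype identity key `(cdr3_nt, v_call, j_call, c_call[, cell])`
  with read-count merging; classification into the isotype hierarchy
  (heavy/light → IGHA/D/E/G/M → IGHG1–4, IGHA1–2); productive-chain
  filtering.
* **Repertoire statistics** — clonality bins (0–1, 2–10, 11–50, 51–100,
  ≥101 copies), absolute abundance, and the diversity statistic
  `CPK = 1000 · n_clonotypes / n_reads` at every hierarchy level;
  normality-gated group comparisons (Student t vs Wilcoxon, gated by
  Shapiro–Wilk at α = 0.05) with expansion folds defined as ratios of
  group means.
* **IGHV usage** — usage matrices at gene (allele-trimmed) resolution, the
  low-expression exclusion rule (drop a gene low in ≥ 10 % of the
  reference group's samples, complementary reading available), ranked top
  genes and cross-dataset intersections.
* **Candidate-gene discovery** — the three-criterion intersection that
  flags a key gene: |r| > 0.7 with IGHG clonotype abundance, |r| > 0.7
  with IGHG CPK, and Hochberg-adjusted differential expression p < 0.05,
  with all seven Venn-region counts.
* **Cell-type context** — barcode joins against cell-type annotations,
  pooled plasma-vs-B-cell read folds, and correlation of isotype
  abundances with immune-infiltration scores.
* **Graft survival** — Kaplan–Meier, log-rank, high/low stratification at
  arbitrary `a:b` ratios (top `a/(a+b)` fraction is "high", ties to high),
  and multivariate Cox regression (Efron ties) reporting per-unit hazard
  ratios.
* **Synthetic cohorts** — a generator that emulates the cohort structure
  these analyses assume (18 TCMR / 16 STA, 38-fold total expansion,
  51-fold IgG1 expansion, a 993/620/76 naive-B/memory-B/plasma single-cell
  sample with a 182-fold plasma:B read ratio, implanted candidate genes
  with fixed correlations 0.891 / −0.703, survival with true HR 2.421)
  with machine-readable ground truth, so every statistic above has a
  parameter-recovery test.

## Worked example

```r
library(graftBCR)

cfg <- synthetic_config(seed = 101)          # study-shaped defaults
coh <- generate_repertoire_cohort(cfg)
coh$samples[[1]]
#> <repertoire_sample> TCMR_01 [TCMR, bulk]: 334 clonotypes, 3192 reads

sm <- summarize_cohort(coh$samples)
compare_groups(sm, "reads", "total", "TCMR", "STA")
#> # A tibble: 1 x 11
#>   metric level group_a group_b   n_a   n_b mean_a mean_b  fold test      p_value
#>   <chr>  <chr> <chr>   <chr>   <int> <int>  <dbl>  <dbl> <dbl> <chr>       <dbl>
#> 1 reads  total TCMR    STA        18    16  6695.   146.  45.7 wilcoxon 9.07e-10

compare_groups(sm, "cpk", "IGHG", "TCMR", "STA")
#> 1 cpk    IGHG  TCMR    STA        18    16   73.3   785. 0.0934 wilcoxon 6.70e-7
```

The first comparison estimates a 45.7-fold total read expansion in TCMR on
this draw (the generator's expected fold is 38; single-cohort estimates
scatter around it). The second shows IGHG diversity collapsing in TCMR —
CPK 73 versus 785 clonotypes per thousand reads — the signature of clonal
expansion: many reads concentrated in few clones.

Candidate-gene discovery on the same cohort:

```r
ex <- generate_expression(cfg, sm)
ca <- correlate_with_metric(ex$expr, ex$metrics$abundance, method = "pearson")
cc <- correlate_with_metric(ex$expr, ex$metrics$cpk, method = "pearson")
de <- differential_expression(ex$expr, ex$groups)
select_candidates(ca, cc, de)$selected
#> [1] "implant_1"
```

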