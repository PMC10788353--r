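make_small_cohort <- function(seed, ...) {
  args <- list(n_cancers = 2L, samples_per_cancer = 60L,
               n_normal_pairs = 20L, n_genes = 60L,
               hypoxia_signature_size = 10L,
               stromal_signature_size = 8L,
               immune_signature_size = 8L,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  generate_cohort(do.call(cohort_spec, args))
}

test_that("tumor-vs-normal applies the normal-sample eligibility rule", {
  co <- make_small_cohort(1)
  cfg <- analysis_config()
  # 20 normals per cancer: both cancers eligible, 5 genes each
  tab <- suppressMessages(tumor_vs_normal(co$expression, co$clinical, cfg))
  expect_setequal(unique(tab$grouping), c("CA01", "CA02"))
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$adj_p >= tab$p_value - 1e-15))

  # a cancer with only 5 normals is excluded
  cl5 <- co$clinical
  drop_n <- cl5$sample_id[cl5$tissue == "normal" & cl5$cancer_type == "CA02"][1:15]
  cl5 <- cl5[!cl5$sample_id %in% drop_n, ]
  tab5 <- suppressMessages(tumor_vs_normal(co$expression, cl5, cfg))
  expect_false("CA02" %in% tab5$grouping)
})

test_that("planted tumor shifts are detected with the right direction", {
  hits <- vapply(1:20, function(s) {
    co <- make_small_cohort(s, n_normal_pairs = 30L,
                            de_shifts = c(VEGFA = 1.5, VEGFB = 0.3,
                                          VEGFC = 0.5, VEGFD = -0.5,
                                          PGF = 0.8))
    tab <- suppressMessages(tumor_vs_normal(co$expression, co$clinical,
                                            analysis_config()))
    row <- tab[tab$unit == "VEGFA" & tab$grouping == "CA01", ]
    row$adj_p < 0.05 && row$direction > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("hypoxia correlation recovers planted loadings per cancer", {
  co <- make_small_cohort(3)
  hs <- binary_hypoxia_score(co$expression, co$signatures$hypoxia)
  tab <- suppressMessages(correlate_expression_with_hypoxia(
    co$expression, hs, co$clinical, analysis_config()))
  expect_setequal(unique(tab$score_kind), "hypoxia")
  a <- tab[tab$unit == "VEGFA", ]
  d <- tab[tab$unit == "VEGFD", ]
  expect_true(all(a$statistic > 0))
  expect_true(all(d$statistic < 0))
  expect_true(all(a$adj_p < 0.05))
  # null gene stays near zero on average
  b <- tab[tab$unit == "VEGFB", ]
  expect_lt(mean(abs(b$statistic)), 0.25)
})

test_that("miRNA-hypoxia correlation respects the user-supplied map", {
  co <- make_small_cohort(4)
  hs <- binary_hypoxia_score(co$expression, co$signatures$hypoxia)
  cfg <- analysis_config(mirna_target_map = vegf_mirna_target_map())
  tab <- suppressMessages(correlate_mirna_with_hypoxia(
    co$mirna, hs, co$clinical, cfg))
  neg <- tab[tab$unit == "hsa-miR-101-3p", ]
  pos <- tab[tab$unit == "hsa-miR-130b-5p", ]
  expect_true(all(neg$statistic < 0))
  expect_true(all(pos$statistic > 0))
  expect_true(grepl("VEGFA", neg$target_gene[1]))

  # empty map: empty table, no error
  empty <- correlate_mirna_with_hypoxia(co$mirna, hs, co$clinical,
                                        analysis_config())
  expect_equal(nrow(empty), 0L)
  # map referencing unknown miRNAs only: empty table + warning
  cfg_bad <- analysis_config(mirna_target_map = list(VEGFA = "hsa-miR-ghost"))
  expect_warning(
    out <- correlate_mirna_with_hypoxia(co$mirna, hs, co$clinical, cfg_bad),
    "absent")
  expect_equal(nrow(out), 0L)
})

test_that("TME correlation emits all three score kinds and surfaces skips", {
  co <- make_small_cohort(5)
  est <- estimate_scores(co$expression, co$signatures$stromal,
                         co$signatures$immune)
  cfg <- analysis_config()
  tab <- suppressMessages(correlate_expression_with_tme(
    co$expression, est, co$clinical, cfg))
  expect_setequal(unique(tab$score_kind),
                  c("stromal_score", "immune_score", "estimate_score"))
  expect_equal(nrow(tab), 5L * 2L * 3L)
  # planted stromal coupling on VEGFC comes back positive
  vc <- tab[tab$unit == "VEGFC" & tab$score_kind == "stromal_score", ]
  expect_true(all(vc$statistic > 0))

  # constant gene is surfaced as a skipped row with a reason
  m <- co$expression
  m["VEGFB", ] <- 3.14
  tab2 <- suppressMessages(correlate_expression_with_tme(m, est, co$clinical, cfg))
  skipped <- tab2[tab2$unit == "VEGFB", ]
  expect_true(all(is.na(skipped$statistic)))
  expect_true(all(grepl("zero rank variance", skipped$note)))
})

test_that("subtype and stage comparisons detect planted group shifts", {
  co <- make_small_cohort(6, samples_per_cancer = 150L,
                          subtype_shifts = list(VEGFC = c(C3 = 1, C6 = 1)),
                          stage_slopes = c(VEGFA = 0.5))
  cfg <- analysis_config()
  st <- suppressMessages(subtype_differential(co$expression, co$subtypes,
                                              co$clinical, cfg))
  vc <- st[st$unit == "VEGFC", ]
  meds <- as.matrix(vc[, paste0("median_C", 1:6)])
  # planted +0.7 shift in C3 and C6: their medians dominate
  expect_true(all(apply(meds, 1, function(m)
    max(m[c(3, 6)], na.rm = TRUE) >= max(m[-c(3, 6)], na.rm = TRUE))))
  expect_true(all(vc$adj_p < 0.05))

  sg <- suppressMessages(stage_differential(co$expression, co$clinical, cfg))
  va <- sg[sg$unit == "VEGFA", ]
  expect_true(all(va$adj_p < 0.05))
  med_mat <- as.matrix(va[, c("median_I", "median_II", "median_III", "median_IV")])
  expect_true(all(apply(med_mat, 1, function(m) m["median_IV"] > m["median_I"])))
})

test_that("absent subtypes are dropped from the test rather than failing", {
  co <- make_small_cohort(7)
  sub <- co$subtypes[co$subtypes$subtype != "C5", ]
  tab <- suppressMessages(subtype_differential(co$expression, sub, co$clinical,
                                               analysis_config()))
  expect_true(all(is.na(tab$median_C5)))
  expect_gt(nrow(tab), 0L)
})

test_that("stages with too few samples reduce to the remaining groups", {
  co <- make_small_cohort(8)
  cl <- co$clinical
  # restrict one cancer to stages I/II only
  idx <- cl$cancer_type == "CA01" & cl$tissue == "tumor"
  cl$stage[idx] <- factor(rep(c("I", "II"), length.out = sum(idx)),
                          levels = levels(cl$stage))
  tab <- suppressMessages(stage_differential(co$expression, cl,
                                             analysis_config()))
  ca1 <- tab[tab$grouping == "CA01", ]
  expect_true(all(is.na(ca1$median_III)))
  expect_true(all(!is.na(ca1$median_I)))
})

test_that("stages do not mutate the shared expression matrix", {
  co <- make_small_cohort(9)
  before <- digest_matrix(co$expression)
  hs <- binary_hypoxia_score(co$expression, co$signatures$hypoxia)
  est <- estimate_scores(co$expression, co$signatures$stromal,
                         co$signatures$immune)
  cfg <- analysis_config(mirna_target_map = vegf_mirna_target_map())
  suppressMessages({
    tumor_vs_normal(co$expression, co$clinical, cfg)
    correlate_expression_with_hypoxia(co$expression, hs, co$clinical, cfg)
    correlate_expression_with_tme(co$expression, est, co$clinical, cfg)
    subtype_differential(co$expression, co$subtypes, co$clinical, cfg)
    stage_differential(co$expression, co$clinical, cfg)
    survival_analysis(co$expression, co$clinical, genes = cfg$target_genes)
  })
  expect_identical(digest_matrix(co$expression), before)
})

test_that("full pipeline run writes every stage and is byte-identical on rerun", {
  co <- make_small_cohort(10)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  cfg <- list(inputs = list(expression = file.path(d, "expression.tsv"),
                            clinical = file.path(d, "clinical.tsv"),
                            mirna = file.path(d, "mirna.tsv"),
                            subtypes = file.path(d, "subtypes.tsv"),
                            signatures = file.path(d, "signatures.gmt")),
              targets = list(mirna_target_map = vegf_mirna_target_map()),
              seed = 11)
  out1 <- file.path(d, "run1"); out2 <- file.path(d, "run2")
  res <- run_full_analysis(cfg, out1)
  expect_setequal(names(res$results),
                  c("de", "hypoxia_corr", "mirna_corr", "tme_corr",
                    "subtype_kw", "stage_kw", "survival"))
  files <- c("de.tsv", "hypoxia_corr.tsv", "mirna_corr.tsv", "tme_corr.tsv",
             "subtype_kw.tsv", "stage_kw.tsv", "survival.tsv", "manifest.json")
  expect_true(all(file.exists(file.path(out1, files))))

  run_full_analysis(cfg, out2)
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  expect_equal(length(res$manifest$failures), 0L)
})

test_that("pipeline fails fast on a missing expression path", {
  cfg <- list(inputs = list(expression = "/nonexistent/expr.tsv",
                            clinical = "/nonexistent/clin.tsv"))
  d <- withr::local_tempdir()
  expect_error(run_full_analysis(cfg, file.path(d, "out")), "not found")
  expect_false(dir.exists(file.path(d, "out")))
})

test_that("independent stages complete when one input is absent", {
  co <- make_small_cohort(12)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  cfg <- list(inputs = list(expression = file.path(d, "expression.tsv"),
                            clinical = file.path(d, "clinical.tsv"),
                            signatures = file.path(d, "signatures.gmt")),
              seed = 1)
  res <- run_full_analysis(cfg, file.path(d, "out"))
  expect_true(all(c("de", "hypoxia_corr", "stage_kw", "survival") %in%
                    names(res$results)))
  expect_true(all(c("mirna_corr", "subtype_kw") %in% names(res$manifest$failures)))
})
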