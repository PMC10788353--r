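test_that("rank profile orders genes with the lexicographic tie rule", {
  m <- toy_matrix(c(3, 1, 2), c("A", "B", "C"), "S1")
  p <- rank_profile(m, "S1")
  expect_equal(p$ordered_genes, c("A", "C", "B"))
  expect_equal(p$rank_of, c(A = 3L, C = 2L, B = 1L))

  # ties: the lexicographically smaller gene receives the lower rank
  m2 <- toy_matrix(c(2, 2), c("A", "B"), "S")
  p2 <- rank_profile(m2, "S")
  expect_equal(p2$ordered_genes, c("B", "A"))
  expect_equal(p2$rank_of[["A"]], 1L)

  # permuting input gene order leaves the profile unchanged
  m3 <- toy_matrix(rnorm(3), c("g3", "g1", "g2"), "S")
  m3p <- m3[c(2, 3, 1), , drop = FALSE]
  expect_equal(rank_profile(m3, "S")$rank_of[sort(rownames(m3))],
               rank_profile(m3p, "S")$rank_of[sort(rownames(m3))])

  expect_error(rank_profile(m, "nope"), "not found")
  m[1, 1] <- NA
  expect_error(rank_profile(m, "S1"), "missing values")
})

test_that("enrichment score reproduces the worked four-gene values", {
  p <- toy_profile()
  expect_equal(enrichment_score(p, "A", alpha = 0.25)$es, 2.0)
  expect_equal(enrichment_score(p, "D", alpha = 0.25)$es, -2.0)
  es_ac <- enrichment_score(p, c("A", "C"), alpha = 0.25)
  expect_equal(es_ac$es,
               (4^0.25 / (4^0.25 + 2^0.25)) +
                 (4^0.25 / (4^0.25 + 2^0.25) - 1 / 2) + 1 / 2 + 0)
  expect_equal(es_ac$es, 1.086428, tolerance = 1e-6)
  expect_equal(es_ac$n_s, 2L)
})

test_that("enrichment score rejects degenerate signatures and bad alpha", {
  p <- toy_profile()
  expect_error(enrichment_score(p, "Z"), "disjoint")
  expect_error(enrichment_score(p, LETTERS[1:4]), "covers all genes")
  expect_error(enrichment_score(p, "A", alpha = 0), "positive")
  # absent signature genes are dropped and recorded
  res <- enrichment_score(p, c("A", "Z1", "Z2"))
  expect_equal(res$n_s, 1L)
  expect_equal(res$es, 2.0)
})

test_that("enrichment score matches the brute-force summation on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:20, 1)
    genes <- sprintf("g%02d", seq_len(n))
    m <- toy_matrix(rnorm(n), genes, "S")
    p <- rank_profile(m, "S")
    n_s <- sample(seq_len(n - 1), 1)
    sig <- sample(genes, n_s)
    for (alpha in c(0.1, 0.25, 1)) {
      expect_equal(enrichment_score(p, sig, alpha)$es,
                   oracle_es(p$ordered_genes, sig, alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment score is invariant under strictly increasing transforms", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(5:15, 1)
    genes <- sprintf("g%02d", seq_len(n))
    v <- rnorm(n)
    sig <- sample(genes, sample(seq_len(n - 1), 1))
    p1 <- rank_profile(toy_matrix(v, genes, "S"), "S")
    p2 <- rank_profile(toy_matrix(exp(2 * v) + 5, genes, "S"), "S")
    expect_identical(enrichment_score(p1, sig)$es, enrichment_score(p2, sig)$es)
  }
})

test_that("top-position signature attains the maximal ES among equal-size sets", {
  set.seed(11)
  n <- 8
  genes <- sprintf("g%d", 1:n)
  p <- rank_profile(toy_matrix(rnorm(n), genes, "S"), "S")
  for (n_s in c(2, 3)) {
    top_sig <- p$ordered_genes[seq_len(n_s)]
    es_top <- enrichment_score(p, top_sig)$es
    all_sets <- utils::combn(genes, n_s)
    es_all <- apply(all_sets, 2, function(s) enrichment_score(p, s)$es)
    expect_equal(es_top, max(es_all))
  }
})

test_that("uniform-weight limit flips sign when the ordering is reversed", {
  set.seed(3)
  n <- 12
  genes <- sprintf("g%02d", 1:n)
  v <- sample(seq_len(n))            # distinct values, no tie-break asymmetry
  p_fwd <- rank_profile(toy_matrix(v, genes, "S"), "S")
  p_rev <- rank_profile(toy_matrix(-v, genes, "S"), "S")
  sig <- p_fwd$ordered_genes[1:4]
  es_fwd <- enrichment_score(p_fwd, sig, alpha = 1e-6)$es
  es_rev <- enrichment_score(p_rev, sig, alpha = 1e-6)$es
  expect_equal(es_rev, -es_fwd, tolerance = 1e-4)
})

test_that("cohort scoring emits one row per sample-signature pair", {
  m <- toy_matrix(rnorm(12), sprintf("g%d", 1:4), c("s1", "s2", "s3"))
  res <- score_cohort_ssgsea(m, list(sigA = c("g1", "g2"), sigB = "g3"))
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$signature_name), c("sigA", "sigB"))
  # per-sample monotone transform leaves that sample's scores unchanged
  m2 <- m
  m2[, "s2"] <- 10 * m2[, "s2"] + 3
  res2 <- score_cohort_ssgsea(m2, list(sigA = c("g1", "g2"), sigB = "g3"))
  expect_equal(res2$es[res2$sample_id == "s2"], res$es[res$sample_id == "s2"])
})

test_that("estimate scores are the additive stromal + immune composite", {
  set.seed(5)
  m <- toy_matrix(rnorm(16), sprintf("g%d", 1:8), c("s1", "s2"))
  st <- c("g1", "g2"); im <- c("g5", "g6")
  es <- estimate_scores(m, st, im)
  expect_equal(es$estimate_score, es$stromal_score + es$immune_score)
  # components agree with enrichment_score run alone
  p <- rank_profile(m, "s1")
  expect_equal(es$stromal_score[es$sample_id == "s1"],
               enrichment_score(p, st)$es)
  expect_equal(es$immune_score[es$sample_id == "s1"],
               enrichment_score(p, im)$es)
  expect_warning(estimate_scores(m, c("g1", "g2"), c("g2", "g5")), "share")
})

test_that("all-equal expression gives identical tie-broken scores across samples", {
  m <- toy_matrix(rep(1, 12), sprintf("g%d", 1:6), c("s1", "s2"))
  res <- score_cohort_ssgsea(m, list(sig = c("g2", "g4")))
  expect_equal(res$es[1], res$es[2])
  p <- rank_profile(m, "s1")
  expect_equal(res$es[1], oracle_es(p$ordered_genes, c("g2", "g4"), 0.25))
})

test_that("binary hypoxia score applies the +1/-1 pooled-median rule", {
  mh <- toy_matrix(c(1, 1, 2, 2, 3, 4, 4, 3), c("g1", "g2"),
                   sprintf("s%d", 1:4))
  res <- binary_hypoxia_score(mh, c("g1", "g2"))
  expect_equal(res$score, c(-2L, -2L, 2L, 2L))
  expect_equal(res$n_used, rep(2L, 4))
  expect_equal(res$ties_at_median, rep(0L, 4))

  # single gene, distinct values, even n: exactly half the samples score +1
  m1 <- toy_matrix(c(5, 1, 9, 3), "g1", sprintf("s%d", 1:4))
  r1 <- binary_hypoxia_score(m1, "g1")
  expect_equal(sum(r1$score == 1L), 2L)

  expect_error(binary_hypoxia_score(mh, "zz"), "disjoint")
  expect_error(binary_hypoxia_score(mh[, 1, drop = FALSE], "g1"), "single sample")
})

test_that("hypoxia score bounds, parity and negation symmetry hold on random cohorts", {
  set.seed(99)
  for (rep in 1:40) {
    n_g <- 6; n_s <- 10
    m <- toy_matrix(rnorm(n_g * n_s), sprintf("g%d", 1:n_g),
                    sprintf("s%02d", 1:n_s))
    sig <- sprintf("g%d", 1:4)
    res <- binary_hypoxia_score(m, sig)
    expect_true(all(abs(res$score) <= res$n_used))
    expect_true(all((res$score - res$n_used) %% 2 == 0))
    if (all(res$ties_at_median == 0)) {
      neg <- binary_hypoxia_score(-m, sig)
      expect_equal(neg$score, -res$score)
    }
  }
})

test_that("hypoxia scoring is deterministic across runs", {
  set.seed(1)
  m <- toy_matrix(rnorm(60), sprintf("g%d", 1:6), sprintf("s%d", 1:10))
  expect_identical(binary_hypoxia_score(m, c("g1", "g2", "g3")),
                   binary_hypoxia_score(m, c("g1", "g2", "g3")))
  expect_identical(score_cohort_ssgsea(m, list(s = c("g1", "g2"))),
                   score_cohort_ssgsea(m, list(s = c("g1", "g2"))))
})
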