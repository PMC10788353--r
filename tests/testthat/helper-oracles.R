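# Independent brute-force oracles and small fixture builders. The oracles
# deliberately re-derive each quantity from its printed definition (explicit
# per-position/per-pattern loops) and share no code with the implementation.

# Enrichment score by literal term-by-term evaluation of the double summation.
oracle_es <- function(ordered_genes, signature, alpha) {
  n <- length(ordered_genes)
  rank_at <- seq(n, 1)                 # rank of the gene at position i
  in_sig <- ordered_genes %in% signature
  n_s <- sum(in_sig)
  denom <- sum(rank_at[in_sig]^alpha)
  es <- 0
  for (i in seq_len(n)) {
    p_sw <- sum(rank_at[seq_len(i)][in_sig[seq_len(i)]]^alpha) / denom
    p_ns <- sum(!in_sig[seq_len(i)]) / (n - n_s)
    es <- es + (p_sw - p_ns)
  }
  es
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# patterns (average ranks for tied magnitudes, zeros already removed).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  ws <- as.numeric(signs %*% r)
  mean(abs(ws) >= abs(w_obs) - 1e-9)
}

# Kruskal-Wallis H from its definition with the tie correction factor.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n_tot <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(sizes * rbar^2) - 3 * (n_tot + 1)
  tie <- table(x)
  h / (1 - sum(tie^3 - tie) / (n_tot^3 - n_tot))
}

# BH step-up from its definition: q_(i) = min_{j>=i} p_(j) * m / j, capped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Cox log-hazard for untied two-group data by direct maximization of the
# partial likelihood (Breslow form; valid when event times are untied).
oracle_cox_loghr <- function(times, events, x) {
  logpl <- function(b) {
    s <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  stats::optimize(logpl, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# Small deterministic expression matrix with named genes/samples.
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes),
         dimnames = list(genes, samples))
}

# Four-gene single-sample profile with ranks 4..1 for genes A..D.
toy_profile <- function() {
  rank_profile(toy_matrix(c(4, 3, 2, 1), LETTERS[1:4], "S1"), "S1")
}

# Minimal low-overhead null cohort spec used by calibration tests: one
# cancer, one null target gene, small signatures.
null_spec <- function(seed, samples = 120L, pairs = 24L) {
  cohort_spec(n_cancers = 1L, samples_per_cancer = samples,
              n_normal_pairs = pairs, n_genes = 25L,
              hypoxia_signature_size = 10L,
              stromal_signature_size = 5L, immune_signature_size = 5L,
              gene_loadings = c(VEGFA = 0), de_shifts = c(VEGFA = 0),
              survival_log_hr = c(VEGFA = 0),
              subtype_shifts = list(), stage_slopes = c(VEGFA = 0),
              stromal_loadings = c(VEGFA = 0), immune_loadings = c(VEGFA = 0),
              mirna_loadings = c("hsa-miR-null-a" = 0), n_null_mirnas = 0L,
              frac_stage_unknown = 0, seed = seed)
}

single_gene_config <- function() {
  analysis_config(target_genes = "VEGFA")
}

# Cheap content checksum for mutation checks.
digest_matrix <- function(m) {
  list(dn = dimnames(m), s1 = sum(m), s2 = sum(m * seq_along(m)))
}
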