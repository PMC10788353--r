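# Per-sample signature scoring: the rank-weighted single-sample enrichment
# score (ssGSEA-style, used for stromal/immune/ESTIMATE scores) and the
# binary +1/-1 median-split hypoxia score over a pooled multi-cancer cohort.

#' Rank profile of one sample
#'
#' Orders the genes of a single sample from highest to lowest expression and
#' assigns integer ranks: the top gene gets rank `n`, the bottom gene rank 1.
#' Ties in expression are broken by gene identifier so that the
#' lexicographically smaller gene receives the LOWER rank; the ordering is
#' therefore total and the profile deterministic.
#'
#' @param matrix genes x samples expression matrix (complete for `sample`).
#' @param sample sample identifier (a column of `matrix`).
#' @return object of class `ranked_profile`: list with `sample_id`,
#'   `ordered_genes` (highest rank first), `rank_of` (named integer vector,
#'   a permutation of `1:n`), and `n`.
#' @export
rank_profile <- function(matrix, sample) {
  validate_expression_matrix(matrix, allow_missing = TRUE)
  if (!sample %in% colnames(matrix))
    stop("sample '", sample, "' not found in matrix")
  v <- matrix[, sample]
  if (anyNA(v))
    stop("sample '", sample,
         "' has missing values; impute or filter before ranking")
  genes <- rownames(matrix)
  # High-to-low by value; among ties the lexicographically larger gene comes
  # first, so the smaller gene ends lower in the ordering (= lower rank).
  o <- order(-v, -xtfrm(genes))
  ordered_genes <- genes[o]
  n <- length(genes)
  rank_of <- stats::setNames(seq(n, 1L), ordered_genes)
  structure(list(sample_id = sample, ordered_genes = ordered_genes,
                 rank_of = rank_of, n = n),
            class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat("Ranked sample profile:", x$sample_id, "(", x$n, "genes )\n")
  k <- min(5L, x$n)
  cat("  top:", paste(x$ordered_genes[seq_len(k)], collapse = ", "), "\n")
  invisible(x)
}

#' Single-sample enrichment score ES(S, T)
#'
#' For a signature S of n_S genes and a sample T whose n genes are ordered by
#' rank from highest (rank n) to lowest (rank 1), the enrichment score is the
#' sum over positions i = 1..n of the difference between the weighted
#' empirical CDF of the signature genes and the empirical CDF of the
#' non-signature genes:
#'
#'   ES(S,T) = sum_i \[ P_Sw(i) - P_nS(i) \]
#'   P_Sw(i) = sum_{j in S, j <= i} r_j^alpha / sum_{j in S} r_j^alpha
#'   P_nS(i) = #\{non-signature genes at positions <= i\} / (n - n_S)
#'
#' with `alpha` weighting the ranks (default 0.25). Signature genes absent
#' from the profile are dropped and the size actually used is returned as
#' `n_s`.
#'
#' @param profile a [rank_profile()] result.
#' @param signature character vector of signature gene identifiers.
#' @param alpha positive rank-weight exponent; default 0.25.
#' @param signature_name optional label carried into the result.
#' @return list with `sample_id`, `signature_name`, `es`, `alpha`, `n_s`.
#' @export
enrichment_score <- function(profile, signature, alpha = 0.25,
                             signature_name = NA_character_) {
  stopifnot(inherits(profile, "ranked_profile"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  sig <- unique(signature)
  in_sig <- profile$ordered_genes %in% sig
  n <- profile$n
  n_s <- sum(in_sig)
  if (n_s == 0L)
    stop("signature disjoint from matrix")
  if (n_s == n)
    stop("signature covers all genes (non-signature ECDF undefined)")
  r <- seq(n, 1L)                       # rank of the gene at position i
  w <- ifelse(in_sig, r^alpha, 0)
  p_sw <- cumsum(w) / sum(w)
  p_ns <- cumsum(!in_sig) / (n - n_s)
  es <- sum(p_sw - p_ns)
  list(sample_id = profile$sample_id, signature_name = signature_name,
       es = es, alpha = alpha, n_s = n_s)
}

#' Cohort-wide single-sample enrichment scores
#'
#' Applies [enrichment_score()] to every (sample, signature) pair. Because the
#' score depends on expression only through within-sample ranks, any strictly
#' increasing transform of a sample's expression leaves its scores unchanged.
#'
#' @param matrix complete genes x samples expression matrix.
#' @param signatures named list of character vectors.
#' @param alpha rank-weight exponent, default 0.25.
#' @return `data.frame` with columns `sample_id`, `signature_name`, `es`,
#'   `alpha`, `n_s` (one row per sample x signature).
#' @export
score_cohort_ssgsea <- function(matrix, signatures, alpha = 0.25) {
  validate_expression_matrix(matrix)
  if (is.character(signatures)) signatures <- list(signature = signatures)
  if (is.null(names(signatures)) || any(!nzchar(names(signatures))))
    stop("signatures must be a named list")
  rows <- vector("list", ncol(matrix) * length(signatures))
  k <- 0L
  for (s in colnames(matrix)) {
    prof <- rank_profile(matrix, s)
    for (nm in names(signatures)) {
      k <- k + 1L
      rows[[k]] <- tryCatch(
        as.data.frame(enrichment_score(prof, signatures[[nm]], alpha = alpha,
                                       signature_name = nm),
                      stringsAsFactors = FALSE),
        error = function(e) stop("sample '", s, "', signature '", nm, "': ",
                                 conditionMessage(e)))
    }
  }
  do.call(rbind, rows)
}

#' Stromal, immune and combined ESTIMATE-style scores
#'
#' Per sample: `stromal_score = ES(stromal, T)`, `immune_score =
#' ES(immune, T)`, `estimate_score = stromal_score + immune_score`. The
#' composite is used (inversely) as a proxy of tumor purity: more
#' stromal/immune infiltration, lower purity.
#'
#' @param matrix complete genes x samples expression matrix.
#' @param stromal character vector, stromal signature genes.
#' @param immune character vector, immune signature genes.
#' @param alpha rank-weight exponent, default 0.25.
#' @return `data.frame` with `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`.
#' @export
estimate_scores <- function(matrix, stromal, immune, alpha = 0.25) {
  shared <- intersect(stromal, immune)
  if (length(shared))
    warning("stromal and immune signatures share gene(s): ",
            paste(shared, collapse = ", "))
  es <- score_cohort_ssgsea(matrix,
                            list(stromal = stromal, immune = immune),
                            alpha = alpha)
  wide <- data.frame(
    sample_id = colnames(matrix),
    stromal_score = es$es[es$signature_name == "stromal"][
      match(colnames(matrix), es$sample_id[es$signature_name == "stromal"])],
    immune_score = es$es[es$signature_name == "immune"][
      match(colnames(matrix), es$sample_id[es$signature_name == "immune"])],
    stringsAsFactors = FALSE)
  wide$estimate_score <- wide$stromal_score + wide$immune_score
  wide
}

#' Binary +1/-1 hypoxia score
#'
#' For each signature gene the median of its expression is taken over ALL
#' samples of the pooled (multi-cancer) cohort. A sample scores +1 for a gene
#' when its value is strictly above that pooled median and -1 otherwise
#' (values exactly at the median score -1 and are counted in
#' `ties_at_median`); the per-sample score is the sum over the signature genes
#' present in the matrix. Scores are therefore integers in
#' `[-n_used, n_used]` with the same parity as `n_used`.
#'
#' The rule is applied per sample against pooled medians: scores from
#' different cancers are comparable because the cohort is pooled before the
#' median split.
#'
#' @param matrix complete genes x samples expression matrix (pooled cohort,
#'   >= 2 samples).
#' @param signature character vector of hypoxia signature genes.
#' @param signature_name label for the output; default "hypoxia".
#' @return `data.frame` with `sample_id`, `signature_name`, `score`,
#'   `n_used`, `ties_at_median`.
#' @export
binary_hypoxia_score <- function(matrix, signature, signature_name = "hypoxia") {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L)
    stop("median split undefined for a single sample")
  genes <- intersect(unique(signature), rownames(matrix))
  if (!length(genes))
    stop("signature disjoint from matrix")
  sub <- matrix[genes, , drop = FALSE]
  med <- apply(sub, 1L, stats::median)
  signs <- ifelse(sub > med, 1L, -1L)   # strictly greater -> +1
  ties <- colSums(sub == med)
  data.frame(sample_id = colnames(matrix),
             signature_name = signature_name,
             score = as.integer(colSums(signs)),
             n_used = length(genes),
             ties_at_median = as.integer(ties),
             stringsAsFactors = FALSE)
}
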