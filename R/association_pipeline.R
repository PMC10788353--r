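# Per-cancer association stages: tumor-vs-normal differential expression,
# gene/miRNA-hypoxia correlation, tumor-microenvironment correlation, immune
# subtype and tumor stage comparisons, and the full-run orchestrator.

#' Analysis configuration
#'
#' @param target_genes genes analyzed at every stage; defaults to the five
#'   VEGF-family angiogenesis genes.
#' @param mirna_target_map named list mapping a target gene to the miRNAs that
#'   target it (user-supplied curation; empty by default).
#' @param min_normal_samples a cancer enters the tumor-vs-normal comparison
#'   only with at least this many normal samples (default 6, i.e. "more than
#'   five").
#' @param alpha_signif significance threshold on BH-adjusted p (default 0.05).
#' @param drug_signif unadjusted p threshold for drug-expression correlations
#'   (default 0.01).
#' @param alpha rank-weight exponent of the enrichment score (default 0.25).
#' @param bh_family `"per_cancer"` (default) or `"global"`: the family within
#'   which BH adjustment is applied at each stage.
#' @param seed integer seed recorded in the run manifest.
#' @return list of class `panoxia_config`.
#' @export
analysis_config <- function(target_genes = c("VEGFA", "VEGFB", "VEGFC", "VEGFD", "PGF"),
                            mirna_target_map = list(),
                            min_normal_samples = 6L,
                            alpha_signif = 0.05,
                            drug_signif = 0.01,
                            alpha = 0.25,
                            bh_family = c("per_cancer", "global"),
                            seed = 1L) {
  bh_family <- match.arg(bh_family)
  stopifnot(min_normal_samples >= 1L,
            alpha_signif > 0, alpha_signif < 1,
            drug_signif > 0, drug_signif < 1,
            alpha > 0)
  structure(list(target_genes = target_genes,
                 mirna_target_map = mirna_target_map,
                 min_normal_samples = as.integer(min_normal_samples),
                 alpha_signif = alpha_signif, drug_signif = drug_signif,
                 alpha = alpha, bh_family = bh_family,
                 seed = as.integer(seed)),
            class = "panoxia_config")
}

# BH within the configured family; `grouping` is the per-cancer key.
apply_bh <- function(tab, config) {
  if (!nrow(tab)) { tab$adj_p <- numeric(0); return(tab) }
  if (config$bh_family == "global") {
    tab$adj_p <- bh_adjust(tab$p_value)
  } else {
    tab$adj_p <- NA_real_
    for (g in unique(tab$grouping)) {
      idx <- tab$grouping == g
      tab$adj_p[idx] <- bh_adjust(tab$p_value[idx])
    }
  }
  tab
}

empty_assoc <- function(extra = character()) {
  base <- data.frame(unit = character(), grouping = character(),
                     statistic = numeric(), p_value = numeric(),
                     n = integer(), stringsAsFactors = FALSE)
  for (e in extra) base[[e]] <- character(0)
  base
}

#' Curated miRNA target map for the VEGF family
#'
#' Literature-curated miRNAs targeting VEGF-family genes, shipped as a
#' starting map for [correlate_mirna_with_hypoxia()]: miR-101-3p (VEGFA,
#' VEGFC), miR-130b-5p and miR-940 (VEGFB), miR-218-5p (VEGFC), miR-335-5p
#' (VEGFD). Target assignments are configuration, not computed; supply your
#' own map for other panels.
#'
#' @return named list: target gene -> character vector of miRNA identifiers.
#' @export
vegf_mirna_target_map <- function() {
  path <- system.file("extdata", "mirna_vegf_targets.tsv", package = "panoxia")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  split(tab$mirna, tab$target_gene)
}

#' Tumor-versus-normal differential expression
#'
#' For every cancer type with at least `min_normal_samples` normal samples,
#' patient-matched tumor/normal pairs are compared per target gene with the
#' Wilcoxon signed-rank test; p-values are BH-adjusted across genes within
#' each cancer and the direction is reported as mean(tumor) - mean(normal).
#'
#' @param matrix genes x samples expression matrix.
#' @param clinical validated clinical table.
#' @param config [analysis_config()].
#' @return association table: `unit` (gene), `grouping` (cancer),
#'   `statistic` (W), `p_value`, `adj_p`, `n` (pairs), `direction`.
#' @export
tumor_vs_normal <- function(matrix, clinical, config = analysis_config()) {
  validate_expression_matrix(matrix)
  check_sample_overlap(colnames(matrix), clinical$sample_id)
  genes <- intersect(config$target_genes, rownames(matrix))
  cl <- clinical[clinical$sample_id %in% colnames(matrix), , drop = FALSE]
  rows <- list()
  for (ca in sort(unique(as.character(cl$cancer_type)))) {
    sub <- cl[cl$cancer_type == ca, , drop = FALSE]
    n_normal <- sum(sub$tissue == "normal")
    if (n_normal < config$min_normal_samples) next
    tum <- sub[sub$tissue == "tumor", c("sample_id", "patient_id")]
    nor <- sub[sub$tissue == "normal", c("sample_id", "patient_id")]
    paired <- merge(tum, nor, by = "patient_id", suffixes = c("_t", "_n"))
    if (!nrow(paired)) {
      warning("cancer ", ca, ": no patient-matched tumor/normal pairs; skipped")
      next
    }
    for (g in genes) {
      xt <- matrix[g, paired$sample_id_t]
      xn <- matrix[g, paired$sample_id_n]
      res <- tryCatch(suppressMessages(wilcoxon_signed_rank(xt, xn)),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit = g, grouping = ca, statistic = res$statistic,
        p_value = res$p_value, n = nrow(paired),
        direction = mean(xt) - mean(xn), stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    e <- empty_assoc(); e$direction <- numeric(0); e
  }
  apply_bh(tab, config)
}

# Shared per-cancer Spearman engine: correlates each unit (gene/miRNA row of
# `matrix`) against each score column within each cancer's tumor samples.
correlate_with_scores <- function(matrix, scores, clinical, config,
                                  units, score_cols, min_n = 3L) {
  check_sample_overlap(colnames(matrix), clinical$sample_id)
  tum <- clinical[clinical$tissue == "tumor" &
                    clinical$sample_id %in% colnames(matrix) &
                    clinical$sample_id %in% scores$sample_id, , drop = FALSE]
  rows <- list()
  for (ca in sort(unique(as.character(tum$cancer_type)))) {
    ids <- tum$sample_id[tum$cancer_type == ca]
    if (length(ids) < min_n) {
      warning("cancer ", ca, ": fewer than ", min_n,
              " tumor samples; skipped")
      next
    }
    sc <- scores[match(ids, scores$sample_id), , drop = FALSE]
    for (u in units) {
      expr <- matrix[u, ids]
      for (k in score_cols) {
        res <- tryCatch(spearman(expr, sc[[k]]), error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            unit = u, grouping = ca, score_kind = k,
            statistic = NA_real_, p_value = NA_real_, n = length(ids),
            note = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            unit = u, grouping = ca, score_kind = k,
            statistic = res$statistic, p_value = res$p_value, n = res$n,
            note = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    e <- empty_assoc(); e$score_kind <- character(0); e$note <- character(0); e
  }
  apply_bh(tab, config)
}

#' Correlate target-gene expression with hypoxia scores
#'
#' Spearman correlation between each target gene and each hypoxia-signature
#' score, restricted to the tumor samples of each cancer type (scores are
#' computed beforehand on the pooled cohort by [binary_hypoxia_score()]);
#' BH adjustment within each cancer.
#'
#' @param matrix genes x samples expression matrix.
#' @param hypoxia_scores output of [binary_hypoxia_score()] (possibly several
#'   signatures row-bound).
#' @param clinical validated clinical table.
#' @param config [analysis_config()].
#' @return association table with `unit`, `grouping`, `score_kind`
#'   (signature), `statistic` (rho), `p_value`, `adj_p`, `n`.
#' @export
correlate_expression_with_hypoxia <- function(matrix, hypoxia_scores, clinical,
                                              config = analysis_config()) {
  validate_expression_matrix(matrix)
  genes <- intersect(config$target_genes, rownames(matrix))
  sigs <- unique(hypoxia_scores$signature_name)
  tabs <- lapply(sigs, function(sg) {
    sc <- hypoxia_scores[hypoxia_scores$signature_name == sg,
                         c("sample_id", "score")]
    tab <- correlate_with_scores(matrix, sc, clinical, config,
                                 units = genes, score_cols = "score")
    if (nrow(tab)) tab$score_kind <- sg
    tab
  })
  do.call(rbind, tabs)
}

#' Correlate miRNA expression with hypoxia scores
#'
#' Same contract as [correlate_expression_with_hypoxia()] but over the miRNAs
#' of `config$mirna_target_map`; mapped miRNAs absent from the matrix are
#' reported and skipped, and an empty map yields an empty table.
#'
#' @param mirna_matrix miRNAs x samples expression matrix.
#' @param hypoxia_scores output of [binary_hypoxia_score()].
#' @param clinical validated clinical table.
#' @param config [analysis_config()].
#' @return association table (`unit` = miRNA, `target_gene` column added).
#' @export
correlate_mirna_with_hypoxia <- function(mirna_matrix, hypoxia_scores, clinical,
                                         config = analysis_config()) {
  map <- config$mirna_target_map
  empty <- {
    e <- empty_assoc(); e$score_kind <- character(0); e$note <- character(0)
    e$adj_p <- numeric(0); e$target_gene <- character(0); e
  }
  if (!length(map)) return(empty)
  validate_expression_matrix(mirna_matrix)
  mirnas <- unique(unlist(map))
  present <- intersect(mirnas, rownames(mirna_matrix))
  absent <- setdiff(mirnas, present)
  if (length(absent))
    warning("miRNA(s) in target map absent from matrix, skipped: ",
            paste(absent, collapse = ", "))
  if (!length(present)) return(empty)
  sigs <- unique(hypoxia_scores$signature_name)
  tabs <- lapply(sigs, function(sg) {
    sc <- hypoxia_scores[hypoxia_scores$signature_name == sg,
                         c("sample_id", "score")]
    tab <- correlate_with_scores(mirna_matrix, sc, clinical, config,
                                 units = present, score_cols = "score")
    if (nrow(tab)) tab$score_kind <- sg
    tab
  })
  tab <- do.call(rbind, tabs)
  # annotate which target gene(s) each miRNA is curated against
  gene_of <- lapply(stats::setNames(nm = present), function(m)
    names(map)[vapply(map, function(v) m %in% v, logical(1L))])
  tab$target_gene <- vapply(tab$unit, function(m)
    paste(gene_of[[m]], collapse = ","), character(1L))
  tab
}

#' Correlate target-gene expression with tumor-microenvironment scores
#'
#' Spearman correlation of each target gene with the stromal, immune and
#' combined ESTIMATE-style scores within each cancer's tumor samples; a
#' constant gene is surfaced as a row with `NA` statistic and the reason in
#' `note`.
#'
#' @param matrix genes x samples expression matrix.
#' @param estimate_score_table output of [estimate_scores()].
#' @param clinical validated clinical table.
#' @param config [analysis_config()].
#' @return association table with `score_kind` in stromal/immune/estimate.
#' @export
correlate_expression_with_tme <- function(matrix, estimate_score_table, clinical,
                                          config = analysis_config()) {
  validate_expression_matrix(matrix)
  genes <- intersect(config$target_genes, rownames(matrix))
  correlate_with_scores(matrix, estimate_score_table, clinical, config,
                        units = genes,
                        score_cols = c("stromal_score", "immune_score",
                                       "estimate_score"))
}

# Kruskal-Wallis engine over a per-sample categorical label.
kw_differential <- function(matrix, labels_df, clinical, config, label_col,
                            keep_levels = NULL, min_per_group = 2L) {
  validate_expression_matrix(matrix)
  check_sample_overlap(colnames(matrix), labels_df$sample_id)
  genes <- intersect(config$target_genes, rownames(matrix))
  tum_ids <- clinical$sample_id[clinical$tissue == "tumor"]
  df <- labels_df[labels_df$sample_id %in% colnames(matrix) &
                    labels_df$sample_id %in% tum_ids, , drop = FALSE]
  df <- merge(df, clinical[, c("sample_id", "cancer_type")], by = "sample_id")
  lv <- if (is.null(keep_levels)) levels(factor(df[[label_col]])) else keep_levels
  rows <- list()
  for (ca in sort(unique(as.character(df$cancer_type)))) {
    sub <- df[df$cancer_type == ca, , drop = FALSE]
    lab <- as.character(sub[[label_col]])
    keep <- !is.na(lab) & lab %in% lv
    sub <- sub[keep, , drop = FALSE]; lab <- lab[keep]
    cnt <- table(lab)
    use_levels <- names(cnt)[cnt >= min_per_group]
    if (length(use_levels) < 2L) {
      warning("cancer ", ca, ": fewer than 2 usable ", label_col,
              " groups; skipped")
      next
    }
    sub <- sub[lab %in% use_levels, , drop = FALSE]
    lab <- lab[lab %in% use_levels]
    for (g in genes) {
      expr <- matrix[g, sub$sample_id]
      groups <- split(expr, lab)
      res <- tryCatch(kruskal_wallis(groups), error = function(e) NULL)
      if (is.null(res)) next
      row <- data.frame(unit = g, grouping = ca, statistic = res$statistic,
                        p_value = res$p_value, n = res$n,
                        stringsAsFactors = FALSE)
      for (l in lv)
        row[[paste0("median_", l)]] <-
          if (l %in% use_levels) stats::median(groups[[l]]) else NA_real_
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    e <- empty_assoc()
    for (l in lv) e[[paste0("median_", l)]] <- numeric(0)
    e
  }
  apply_bh(tab, config)
}

#' Immune-subtype differential expression
#'
#' Kruskal-Wallis comparison of each target gene across the immune subtypes
#' (C1-C6) present with at least 2 tumor samples in a cancer; BH within
#' cancer; per-subtype medians reported for direction. Absent subtypes are
#' simply left out of the test.
#'
#' @param matrix genes x samples expression matrix.
#' @param subtypes immune-subtype table (see [read_subtypes()]).
#' @param clinical validated clinical table.
#' @param config [analysis_config()].
#' @return association table with per-subtype `median_C1`..`median_C6`.
#' @export
subtype_differential <- function(matrix, subtypes, clinical,
                                 config = analysis_config()) {
  kw_differential(matrix, subtypes, clinical, config, label_col = "subtype",
                  keep_levels = paste0("C", 1:6))
}

#' Tumor-stage differential expression
#'
#' Kruskal-Wallis comparison of each target gene across known major stages
#' I-IV (stage `"unknown"` excluded) with at least 2 samples per stage; BH
#' within cancer; per-stage medians reported.
#'
#' @param matrix genes x samples expression matrix.
#' @param clinical validated clinical table (stage column used).
#' @param config [analysis_config()].
#' @return association table with `median_I`..`median_IV`.
#' @export
stage_differential <- function(matrix, clinical, config = analysis_config()) {
  kw_differential(matrix, clinical[, c("sample_id", "stage")], clinical,
                  config, label_col = "stage",
                  keep_levels = c("I", "II", "III", "IV"))
}
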