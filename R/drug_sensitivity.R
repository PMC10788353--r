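# NCI-60-style drug-response analysis: KNN imputation of the drug-activity
# matrix followed by Pearson correlation of gene expression with drug
# activity across cell lines.

#' KNN imputation of a drug-activity matrix
#'
#' Rows (drugs) with more than `max_missing_frac` missing cells are dropped
#' with a message; rows with no observed value are dropped with a warning.
#' Each remaining missing cell is filled with the mean of that column's
#' observed values over the k nearest rows, where nearness is Euclidean
#' distance on co-observed cells (scaled by the number of co-observed cells so
#' rows with different overlap are comparable). If none of the k neighbors is
#' observed in that column, the column mean of observed values is used.
#'
#' Observed cells are never altered, and a complete matrix is returned
#' unchanged (idempotence).
#'
#' @param activity drugs x cell lines matrix with `NA` for missing.
#' @param k number of neighbor rows (default 10).
#' @param max_missing_frac drop rows missing more than this fraction
#'   (default 0.5).
#' @return complete numeric matrix (possibly fewer rows).
#' @export
knn_impute <- function(activity, k = 10L, max_missing_frac = 0.5) {
  validate_expression_matrix(activity, allow_missing = TRUE)
  if (k < 1L) stop("k must be >= 1")
  miss_frac <- rowMeans(is.na(activity))
  if (any(miss_frac == 1)) {
    warning(sum(miss_frac == 1), " all-missing row(s) dropped: ",
            paste(rownames(activity)[miss_frac == 1], collapse = ", "))
    activity <- activity[miss_frac < 1, , drop = FALSE]
    miss_frac <- rowMeans(is.na(activity))
  }
  if (any(miss_frac > max_missing_frac)) {
    message(sum(miss_frac > max_missing_frac),
            " row(s) dropped for missingness > ", max_missing_frac)
    activity <- activity[miss_frac <= max_missing_frac, , drop = FALSE]
  }
  n <- nrow(activity)
  if (!anyNA(activity)) return(activity)
  if (k >= n)
    stop("k (", k, ") must be smaller than the number of usable rows (", n, ")")
  out <- activity
  col_means <- colMeans(activity, na.rm = TRUE)
  for (i in which(rowSums(is.na(activity)) > 0L)) {
    target <- activity[i, ]
    # scaled Euclidean distance to every other row on co-observed cells
    d <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      shared <- !is.na(target) & !is.na(activity[j, ])
      if (!any(shared)) return(Inf)
      sqrt(mean((target[shared] - activity[j, shared])^2))
    }, numeric(1L))
    nb <- order(d)[seq_len(k)]
    nb <- nb[is.finite(d[nb])]
    for (jc in which(is.na(target))) {
      vals <- activity[nb, jc]
      vals <- vals[!is.na(vals)]
      out[i, jc] <- if (length(vals)) mean(vals) else col_means[jc]
    }
  }
  out
}

#' Gene-drug Pearson correlations across cell lines
#'
#' Correlates each target gene's expression with each drug's activity over
#' the shared cell lines, keeps pairs with `p < threshold_p` (default 0.01)
#' and sorts by |r| descending. Pairs with constant activity (or expression)
#' are skipped with a message.
#'
#' @param cell_line_expr genes x cell lines expression matrix.
#' @param activity complete drugs x cell lines activity matrix (run
#'   [knn_impute()] first if needed).
#' @param genes target gene identifiers; default all expression rows.
#' @param threshold_p retain pairs with `p_value < threshold_p`; use 1 to
#'   keep every pair.
#' @return `data.frame` with `drug_id`, `gene`, `r`, `p_value`,
#'   `n_cell_lines`, sorted by |r| descending.
#' @export
drug_gene_correlations <- function(cell_line_expr, activity,
                                   genes = rownames(cell_line_expr),
                                   threshold_p = 0.01) {
  validate_expression_matrix(cell_line_expr)
  validate_expression_matrix(activity, allow_missing = TRUE)
  shared <- intersect(colnames(cell_line_expr), colnames(activity))
  if (!length(shared))
    stop("no shared cell lines between expression and activity matrices")
  genes <- intersect(genes, rownames(cell_line_expr))
  rows <- list()
  n_skipped <- 0L
  for (g in genes) {
    expr <- cell_line_expr[g, shared]
    for (dr in rownames(activity)) {
      act <- activity[dr, shared]
      ok <- is.finite(expr) & is.finite(act)
      if (sum(ok) < 3L) { n_skipped <- n_skipped + 1L; next }
      res <- tryCatch(pearson(expr[ok], act[ok]), error = function(e) NULL)
      if (is.null(res)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = dr, gene = g, r = res$statistic, p_value = res$p_value,
        n_cell_lines = res$n, stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L)
    message(n_skipped, " gene-drug pair(s) skipped (constant or too few values)")
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug_id = character(), gene = character(), r = numeric(),
               p_value = numeric(), n_cell_lines = integer(),
               stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$p_value) & tab$p_value < threshold_p, , drop = FALSE]
  tab[order(-abs(tab$r)), , drop = FALSE]
}
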