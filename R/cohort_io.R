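#' @keywords internal
"_PACKAGE"

# TSV dialect used throughout: UTF-8, tab-separated, one header row, "NA" and
# the empty string are missing. Matches UCSC-Xena-style exports.

#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique, non-empty gene
#' identifiers as row names and sample identifiers as column names. Values are
#' assumed to be on a log scale (e.g. log2(FPKM+1)); the readers take them as
#' provided. Missing values are allowed only when `allow_missing = TRUE`
#' (drug-panel expression may be incomplete; cohort scoring requires complete
#' data).
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param allow_missing logical; permit `NA` entries.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x, allow_missing = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene row names and sample column names")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (!allow_missing && anyNA(x))
    stop("expression matrix contains missing values")
  if (any(!is.finite(x) & !is.na(x)))
    stop("expression matrix contains non-finite values (Inf/NaN)")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Reads a tab-separated table with one header row and identifiers in the
#' first column. Row identifiers are whitespace-trimmed; matching elsewhere in
#' the package is exact string equality (no alias resolution).
#'
#' @param path file path.
#' @param orientation `"genes_as_rows"` (default) or `"samples_as_rows"`;
#'   the latter is transposed on read so the result is always genes x samples.
#' @param log2p1 apply `log2(x + 1)` to the values (for raw linear-scale
#'   abundance); default `FALSE`, values are taken as already log-scale.
#' @param allow_missing permit missing cells (drug-panel inputs).
#' @return validated numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_as_rows", "samples_as_rows"),
                                   log2p1 = FALSE,
                                   allow_missing = FALSE) {
  orientation <- match.arg(orientation)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expected an identifier column plus at least one data column in ", path)
  ids <- trimws(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]], path))
  if (orientation == "samples_as_rows") num <- t(num)
  if (log2p1) num <- log2(num + 1)
  validate_expression_matrix(num, allow_missing = allow_missing)
  num
}

#' Write an expression matrix to TSV
#'
#' Column order: identifier column (`gene_id`) then samples in matrix order.
#' `write_expression_matrix()` followed by [read_expression_matrix()] is the
#' identity on identifiers and values.
#'
#' @param x genes x samples numeric matrix.
#' @param path output file path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x, allow_missing = TRUE)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' member genes. Duplicate genes within a line are removed with a warning.
#'
#' @param path file path.
#' @return named list of character vectors (one per signature); empty file
#'   gives an empty list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields", i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("signature '%s': %d duplicate gene(s) removed",
                      fields[1L], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (!length(genes))
      stop(sprintf("GMT parse error at line %d: signature '%s' has no genes",
                   i, fields[1L]))
    out[[fields[1L]]] <- genes
  }
  out
}

#' Write gene signatures to a GMT file
#'
#' @param signatures named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of descriptions (recycled
#'   `"na"` otherwise).
#' @export
write_gmt <- function(signatures, path, descriptions = NULL) {
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  if (is.null(descriptions)) descriptions <- rep("na", length(signatures))
  lines <- vapply(seq_along(signatures), function(i) {
    paste(c(names(signatures)[i], descriptions[i], signatures[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

.stage_levels <- c("I", "II", "III", "IV", "unknown")

#' Collapse clinical stage strings to major Roman-numeral stages
#'
#' Sub-stages such as `"Stage IIA"` or `"IIb"` collapse to their major stage
#' (`"II"`). Strings with no recognizable stage map to `"unknown"`.
#'
#' @param stage character vector of stage strings.
#' @return factor with levels I, II, III, IV, unknown.
#' @export
collapse_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  major <- rep("unknown", length(s))
  s[is.na(s)] <- ""
  hit <- regexpr("^(IV|III|II|I)", s)
  major[hit > 0] <- regmatches(s, hit)
  n_unknown <- sum(major == "unknown" & !is.na(stage) & nzchar(trimws(as.character(stage))) &
                     toupper(trimws(as.character(stage))) != "UNKNOWN")
  if (n_unknown > 0)
    message(n_unknown, " unrecognized stage string(s) mapped to 'unknown'")
  factor(major, levels = .stage_levels)
}

#' Read a clinical table from TSV
#'
#' Required columns: `sample_id`, `patient_id`, `cancer_type`, `tissue`
#' (tumor/normal), `os_time` (days), `os_event` (0/1), `stage`. Sub-stages are
#' collapsed to major stages when `collapse_stages = TRUE`. Missing survival is
#' allowed (`NA`) and dropped per-analysis downstream.
#'
#' @param path file path.
#' @param collapse_stages collapse IA/IIB/... to I/II/...; default `TRUE`.
#' @return validated `data.frame`.
#' @export
read_clinical <- function(path, collapse_stages = TRUE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = c("NA", ""), comment.char = "",
                           stringsAsFactors = FALSE)
  validate_clinical(tab, collapse_stages = collapse_stages)
}

#' Validate (and normalize) a clinical table
#'
#' @param tab data.frame with the columns listed under [read_clinical()].
#' @param collapse_stages collapse sub-stages to major stages.
#' @return normalized `data.frame`.
#' @export
validate_clinical <- function(tab, collapse_stages = TRUE) {
  req <- c("sample_id", "patient_id", "cancer_type", "tissue",
           "os_time", "os_event", "stage")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("clinical table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$sample_id <- trimws(as.character(tab$sample_id))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in clinical table: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  if (!all(tab$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  tab$os_time <- as.numeric(tab$os_time)
  if (any(tab$os_time < 0, na.rm = TRUE))
    stop("os_time must be nonnegative")
  tab$os_event <- as.numeric(tab$os_event)
  if (!all(tab$os_event %in% c(0, 1) | is.na(tab$os_event)))
    stop("os_event must be 0 or 1")
  tab$stage <- if (collapse_stages) collapse_stage(tab$stage) else
    factor(as.character(tab$stage), levels = .stage_levels)
  tab
}

#' Read an immune-subtype table from TSV
#'
#' Required columns `sample_id` and `subtype`; subtypes must be one of the six
#' pan-cancer transcriptomic immune classes C1 (wound healing), C2 (IFN-gamma
#' dominant), C3 (inflammatory), C4 (lymphocyte depleted), C5 (immunologically
#' quiet), C6 (TGF-beta dominant).
#'
#' @param path file path.
#' @return `data.frame` with `sample_id` and factor `subtype`.
#' @export
read_subtypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = c("NA", ""), comment.char = "",
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "subtype")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("subtype table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  codes <- paste0("C", 1:6)
  bad <- setdiff(unique(tab$subtype[!is.na(tab$subtype)]), codes)
  if (length(bad))
    stop("invalid immune subtype code(s): ", paste(bad, collapse = ", "),
         " (expected C1-C6)")
  tab$sample_id <- trimws(as.character(tab$sample_id))
  tab$subtype <- factor(tab$subtype, levels = codes)
  tab
}

#' Read a drug-activity matrix (drugs x cell lines) from TSV
#'
#' Missing activity values (`NA` or empty cells) are permitted; all non-finite
#' entries are normalized to `NA`.
#'
#' @param path file path.
#' @return numeric matrix, drugs in rows, cell lines in columns, `NA` marking
#'   missing cells.
#' @export
read_drug_activity <- function(path) {
  m <- read_expression_matrix(path, allow_missing = TRUE)
  m[!is.finite(m)] <- NA_real_
  m
}

#' Write a drug-activity matrix to TSV
#' @param x drugs x cell lines matrix (NAs allowed).
#' @param path output file path.
#' @export
write_drug_activity <- function(x, path) write_expression_matrix(x, path)

#' Write a generic table to TSV with a fixed column order
#' @param tab data.frame.
#' @param path output file path.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared guard: analysis entry points must see overlapping sample sets.
check_sample_overlap <- function(matrix_samples, table_samples, what = "clinical table") {
  if (!length(intersect(matrix_samples, table_samples)))
    stop("no shared sample_id between the expression matrix and the ", what)
  invisible(TRUE)
}
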