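# Full-pipeline orchestrator: scoring plus every association stage, driven by
# a YAML (or in-memory list) configuration, writing one TSV per stage and a
# run manifest.

#' Run the full association pipeline
#'
#' Executes, in order: pooled-cohort hypoxia scoring, stromal/immune/ESTIMATE
#' scoring, tumor-vs-normal differential expression, gene- and miRNA-hypoxia
#' correlation, TME correlation, immune-subtype and stage Kruskal-Wallis
#' comparisons, and median-split survival analysis. Each stage is written as
#' a TSV in `out_dir` (`de.tsv`, `hypoxia_corr.tsv`, `mirna_corr.tsv`,
#' `tme_corr.tsv`, `subtype_kw.tsv`, `stage_kw.tsv`, `survival.tsv`) along
#' with `manifest.json` recording inputs, parameters, seed, package version
#' and any per-stage failure. Independent stages still complete when one
#' fails. Outputs carry no timestamps, so a rerun with the same inputs and
#' seed is byte-identical.
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#'   Sections: `inputs` (paths: `expression`, `clinical`, required;
#'   `mirna`, `subtypes`, `signatures` (GMT), optional), `targets`
#'   (`genes`, `mirna_target_map`, `hypoxia_signatures`, `stromal_signature`,
#'   `immune_signature`), `thresholds` (`alpha_signif`, `drug_signif`,
#'   `min_normal_samples`, `alpha`), `seed`.
#' @param out_dir output directory (created if absent).
#' @return (invisibly) a list of class `panoxia_run` with every stage table
#'   and the manifest.
#' @export
run_full_analysis <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  inputs <- cfg$inputs
  if (is.null(inputs$expression) || is.null(inputs$clinical))
    stop("config must provide inputs$expression and inputs$clinical")
  if (!file.exists(inputs$expression))
    stop("expression file not found: ", inputs$expression)
  if (!file.exists(inputs$clinical))
    stop("clinical file not found: ", inputs$clinical)
  targets <- cfg$targets
  thr <- cfg$thresholds
  acfg <- analysis_config(
    target_genes = targets$genes %||% c("VEGFA", "VEGFB", "VEGFC", "VEGFD", "PGF"),
    mirna_target_map = targets$mirna_target_map %||% list(),
    min_normal_samples = thr$min_normal_samples %||% 6L,
    alpha_signif = thr$alpha_signif %||% 0.05,
    drug_signif = thr$drug_signif %||% 0.01,
    alpha = thr$alpha %||% 0.25,
    seed = cfg$seed %||% 1L)
  set.seed(acfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  expr <- read_expression_matrix(inputs$expression)
  clinical <- read_clinical(inputs$clinical)
  check_sample_overlap(colnames(expr), clinical$sample_id)
  mirna <- if (!is.null(inputs$mirna))
    read_expression_matrix(inputs$mirna) else NULL
  subtypes <- if (!is.null(inputs$subtypes))
    read_subtypes(inputs$subtypes) else NULL
  signatures <- if (!is.null(inputs$signatures))
    read_gmt(inputs$signatures) else list()

  hyp_names <- targets$hypoxia_signatures %||%
    grep("hypoxia", names(signatures), ignore.case = TRUE, value = TRUE)
  stromal_name <- targets$stromal_signature %||%
    grep("stromal", names(signatures), ignore.case = TRUE, value = TRUE)[1L]
  immune_name <- targets$immune_signature %||%
    grep("immune", names(signatures), ignore.case = TRUE, value = TRUE)[1L]

  failures <- list()
  run_stage <- function(name, fun) {
    tryCatch(suppressMessages(fun()), error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  hyp_scores <- run_stage("hypoxia_scoring", function() {
    stopifnot(length(hyp_names) >= 1L)
    do.call(rbind, lapply(hyp_names, function(nm)
      binary_hypoxia_score(expr, signatures[[nm]], signature_name = nm)))
  })
  est_scores <- run_stage("estimate_scoring", function() {
    stopifnot(!is.na(stromal_name), !is.na(immune_name))
    estimate_scores(expr, signatures[[stromal_name]],
                    signatures[[immune_name]], alpha = acfg$alpha)
  })

  stages <- list(
    de = function() tumor_vs_normal(expr, clinical, acfg),
    hypoxia_corr = function() {
      stopifnot(!is.null(hyp_scores))
      correlate_expression_with_hypoxia(expr, hyp_scores, clinical, acfg)
    },
    mirna_corr = function() {
      stopifnot(!is.null(hyp_scores), !is.null(mirna))
      correlate_mirna_with_hypoxia(mirna, hyp_scores, clinical, acfg)
    },
    tme_corr = function() {
      stopifnot(!is.null(est_scores))
      correlate_expression_with_tme(expr, est_scores, clinical, acfg)
    },
    subtype_kw = function() {
      stopifnot(!is.null(subtypes))
      subtype_differential(expr, subtypes, clinical, acfg)
    },
    stage_kw = function() stage_differential(expr, clinical, acfg),
    survival = function() survival_analysis(expr, clinical,
                                            genes = acfg$target_genes))

  results <- list()
  for (nm in names(stages)) {
    tab <- run_stage(nm, stages[[nm]])
    if (!is.null(tab)) {
      results[[nm]] <- tab
      write_tsv(format_stage_table(tab), file.path(out_dir, paste0(nm, ".tsv")))
    }
  }

  manifest <- list(
    package = "panoxia",
    version = as.character(utils::packageVersion("panoxia")),
    seed = acfg$seed,
    inputs = inputs[!vapply(inputs, is.null, logical(1L))],
    parameters = list(target_genes = acfg$target_genes,
                      min_normal_samples = acfg$min_normal_samples,
                      alpha_signif = acfg$alpha_signif,
                      drug_signif = acfg$drug_signif,
                      alpha = acfg$alpha,
                      bh_family = acfg$bh_family,
                      hypoxia_signatures = hyp_names,
                      stromal_signature = stromal_name,
                      immune_signature = immune_name),
    stages_written = names(results),
    failures = failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(list(results = results, manifest = manifest,
                           hypoxia_scores = hyp_scores,
                           estimate_scores = est_scores,
                           out_dir = out_dir),
                      class = "panoxia_run"))
}

# Round-trip-stable numeric formatting so reruns are byte-identical across
# platforms.
format_stage_table <- function(tab) {
  for (j in seq_along(tab))
    if (is.numeric(tab[[j]]))
      tab[[j]] <- vapply(tab[[j]], function(v)
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE),
        character(1L))
  tab
}

#' @export
print.panoxia_run <- function(x, ...) {
  cat("panoxia pipeline run ->", x$out_dir, "\n")
  cat("  stages written:", paste(names(x$results), collapse = ", "), "\n")
  if (length(x$manifest$failures))
    cat("  failures:", paste(names(x$manifest$failures), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
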