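# Synthetic multi-cancer cohorts with planted structure: a latent hypoxia
# axis loading on signature genes, tumor-vs-normal shifts, proportional-
# hazards survival, subtype/stage expression shifts, and NCI-60-style drug
# data with planted gene-drug couplings. Every generated dataset carries a
# truth table so recovery can be scored automatically.

#' Specification of a synthetic cohort
#'
#' Defaults emulate a small multi-cancer study with matched tumor/normal
#' pairs and effect sizes typical of the angiogenesis-gene literature:
#' positive hypoxia coupling for VEGFA/PGF, a negative one for VEGFD,
#' tumor over-expression of all family members except VEGFD, modest
#' prognostic hazards, and VEGFC coupling to stromal/immune infiltration and
#' to the C3/C6 immune subtypes. All effects are overridable; an all-zero
#' setting gives a global-null cohort.
#'
#' @param n_cancers number of cancer types (default 4).
#' @param samples_per_cancer tumor samples per cancer (default 120).
#' @param n_normal_pairs patients per cancer that also contribute a matched
#'   normal sample (default 30).
#' @param n_genes total genes including targets and signatures (default 150).
#' @param hypoxia_signature_size,stromal_signature_size,immune_signature_size
#'   sizes of the three planted signatures (defaults 20, 15, 15; disjoint).
#' @param gene_loadings named vector: target-gene loading on the latent
#'   hypoxia axis.
#' @param signature_loading loading of each hypoxia-signature gene on the
#'   latent axis (default 1), so the binary score tracks the axis.
#' @param de_shifts named vector: tumor-minus-normal log-expression shift.
#' @param survival_log_hr named vector: log hazard ratio per standardized
#'   unit of expression.
#' @param subtype_shifts named list: per gene, a named vector of additive
#'   shifts for immune subtypes C1-C6.
#' @param stage_slopes named vector: additive shift per stage step (stages
#'   I-IV coded 1-4, centered).
#' @param stromal_loadings,immune_loadings named vectors: target-gene loading
#'   on the latent stromal / immune infiltration factors (signature genes
#'   load 1 on their own factor).
#' @param mirna_loadings named vector: miRNA loading on the hypoxia axis
#'   (defaults follow curated miRNA-target couplings: miR-101-3p and
#'   miR-218-5p negative, miR-130b-5p/miR-940/miR-335-5p positive).
#' @param n_null_mirnas additional unassociated miRNAs (default 10).
#' @param baseline_mean,baseline_sd per-gene baseline distribution (log
#'   scale; defaults 5 and 1.5).
#' @param noise_sd residual Gaussian noise SD (default 1).
#' @param censoring_rate target fraction of censored tumor samples
#'   (default 0.3).
#' @param frac_stage_unknown fraction of tumor samples with unknown stage
#'   (default 0.05).
#' @param seed integer RNG seed (Mersenne-Twister).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cancers = 4L,
                        samples_per_cancer = 120L,
                        n_normal_pairs = 30L,
                        n_genes = 150L,
                        hypoxia_signature_size = 20L,
                        stromal_signature_size = 15L,
                        immune_signature_size = 15L,
                        gene_loadings = c(VEGFA = 0.8, VEGFB = 0, VEGFC = 0.4,
                                          VEGFD = -0.4, PGF = 0.6),
                        signature_loading = 1,
                        de_shifts = c(VEGFA = 1.0, VEGFB = 0.3, VEGFC = 0.5,
                                      VEGFD = -0.5, PGF = 0.8),
                        survival_log_hr = c(VEGFA = log(1.5), PGF = log(1.3)),
                        subtype_shifts = list(VEGFC = c(C3 = 0.7, C6 = 0.7)),
                        stage_slopes = c(VEGFA = 0.3),
                        stromal_loadings = c(VEGFC = 0.5),
                        immune_loadings = c(VEGFC = 0.5),
                        mirna_loadings = c("hsa-miR-101-3p" = -0.6,
                                           "hsa-miR-130b-5p" = 0.6,
                                           "hsa-miR-940" = 0.6,
                                           "hsa-miR-218-5p" = -0.6,
                                           "hsa-miR-335-5p" = 0.6),
                        n_null_mirnas = 10L,
                        baseline_mean = 5, baseline_sd = 1.5,
                        noise_sd = 1,
                        censoring_rate = 0.3,
                        frac_stage_unknown = 0.05,
                        seed = 1L) {
  spec <- as.list(environment())
  n_special <- length(spec$gene_loadings) + hypoxia_signature_size +
    stromal_signature_size + immune_signature_size
  if (n_special > n_genes)
    stop("n_genes (", n_genes, ") smaller than targets + signatures (",
         n_special, ")")
  stopifnot(n_cancers >= 1L, samples_per_cancer >= 2L,
            n_normal_pairs >= 0L, n_normal_pairs <= samples_per_cancer,
            noise_sd > 0, censoring_rate >= 0, censoring_rate < 1,
            frac_stage_unknown >= 0, frac_stage_unknown < 1)
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic multi-cancer cohort
#'
#' Per sample a latent hypoxia value `h ~ N(0,1)` and latent stromal/immune
#' infiltration factors `u, v ~ N(0,1)` are drawn. Expression of gene g in
#' sample s is
#' `baseline_g + loading_g * h_s + stromal_g * u_s + immune_g * v_s +
#'  de_shift_g * [tumor] + subtype/stage shift + N(0, noise_sd^2)`.
#' Overall-survival times for tumor samples are exponential with hazard
#' proportional to `exp(sum_g log_hr_g * z(expr_g))`, censored independently
#' at the requested rate, and rounded to whole days (day-resolution ties are
#' deliberate). Outputs are keyed consistently and fully determined by
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `expression` (genes x samples), `mirna`
#'   (miRNAs x samples), `clinical`, `subtypes`, `signatures` (named list:
#'   hypoxia/stromal/immune), and `truth` (planted-effect table).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  targets <- names(spec$gene_loadings)
  hyp_genes <- sprintf("HYPX%03d", seq_len(spec$hypoxia_signature_size))
  str_genes <- sprintf("STRO%03d", seq_len(spec$stromal_signature_size))
  imm_genes <- sprintf("IMMU%03d", seq_len(spec$immune_signature_size))
  n_bg <- spec$n_genes - length(targets) - length(hyp_genes) -
    length(str_genes) - length(imm_genes)
  bg_genes <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character()
  genes <- c(targets, hyp_genes, str_genes, imm_genes, bg_genes)

  cancers <- sprintf("CA%02d", seq_len(spec$n_cancers))
  clin_rows <- list()
  for (ca in cancers) {
    pid <- sprintf("%s-P%04d", ca, seq_len(spec$samples_per_cancer))
    tum <- data.frame(sample_id = paste0(pid, "-T"), patient_id = pid,
                      cancer_type = ca, tissue = "tumor",
                      stringsAsFactors = FALSE)
    clin_rows[[length(clin_rows) + 1L]] <- tum
    if (spec$n_normal_pairs > 0) {
      pidn <- pid[seq_len(spec$n_normal_pairs)]
      clin_rows[[length(clin_rows) + 1L]] <-
        data.frame(sample_id = paste0(pidn, "-N"), patient_id = pidn,
                   cancer_type = ca, tissue = "normal",
                   stringsAsFactors = FALSE)
    }
  }
  clinical <- do.call(rbind, clin_rows)
  n_samp <- nrow(clinical)
  is_tumor <- clinical$tissue == "tumor"

  # latent factors
  h <- stats::rnorm(n_samp)
  u <- stats::rnorm(n_samp)
  v <- stats::rnorm(n_samp)

  # per-sample subtype and stage (tumor only)
  subtype <- rep(NA_character_, n_samp)
  subtype[is_tumor] <- sample(paste0("C", 1:6), sum(is_tumor), replace = TRUE)
  stage <- rep("unknown", n_samp)
  st_draw <- sample(c("I", "II", "III", "IV"), sum(is_tumor), replace = TRUE)
  unk <- stats::runif(sum(is_tumor)) < spec$frac_stage_unknown
  st_draw[unk] <- "unknown"
  stage[is_tumor] <- st_draw
  stage_num <- match(stage, c("I", "II", "III", "IV"))  # NA for unknown

  # effect lookup helpers (0 where unnamed)
  eff <- function(map, gene) if (gene %in% names(map)) unname(map[[gene]]) else 0

  baseline <- stats::rnorm(length(genes), spec$baseline_mean, spec$baseline_sd)
  names(baseline) <- genes
  expr <- base::matrix(stats::rnorm(length(genes) * n_samp, 0, spec$noise_sd),
                       nrow = length(genes),
                       dimnames = list(genes, clinical$sample_id))
  for (g in genes) {
    load_h <- if (g %in% hyp_genes) spec$signature_loading else
      eff(spec$gene_loadings, g)
    load_u <- if (g %in% str_genes) 1 else eff(spec$stromal_loadings, g)
    load_v <- if (g %in% imm_genes) 1 else eff(spec$immune_loadings, g)
    row <- baseline[g] + load_h * h + load_u * u + load_v * v +
      eff(spec$de_shifts, g) * is_tumor
    ss <- spec$subtype_shifts[[g]]
    if (!is.null(ss)) {
      add <- ss[subtype]
      add[is.na(add)] <- 0
      row <- row + add
    }
    sl <- eff(spec$stage_slopes, g)
    if (sl != 0) {
      add <- sl * (stage_num - 2.5)
      add[is.na(add)] <- 0
      row <- row + add
    }
    expr[g, ] <- expr[g, ] + row
  }

  # survival (tumor samples), proportional hazards on standardized expression
  lp <- numeric(sum(is_tumor))
  for (g in names(spec$survival_log_hr)) {
    z <- scale(expr[g, is_tumor])[, 1L]
    lp <- lp + spec$survival_log_hr[[g]] * z
  }
  base_rate <- 1 / 1000                      # events per day
  t_event <- stats::rexp(sum(is_tumor), rate = base_rate * exp(lp))
  cr <- spec$censoring_rate
  os_time <- t_event
  os_event <- rep(1, sum(is_tumor))
  if (cr > 0) {
    t_cens <- stats::rexp(sum(is_tumor), rate = base_rate * cr / (1 - cr))
    os_event <- as.numeric(t_event <= t_cens)
    os_time <- pmin(t_event, t_cens)
  }
  clinical$os_time <- NA_real_
  clinical$os_event <- NA_real_
  clinical$os_time[is_tumor] <- pmax(1, round(os_time))
  clinical$os_event[is_tumor] <- os_event
  clinical$stage <- factor(stage, levels = .stage_levels)

  subtypes <- data.frame(sample_id = clinical$sample_id[is_tumor],
                         subtype = factor(subtype[is_tumor],
                                          levels = paste0("C", 1:6)),
                         stringsAsFactors = FALSE)

  # miRNA matrix over the same samples
  mirna_names <- c(names(spec$mirna_loadings),
                   if (spec$n_null_mirnas > 0)
                     sprintf("hsa-miR-null-%02d", seq_len(spec$n_null_mirnas)))
  mirna <- base::matrix(stats::rnorm(length(mirna_names) * n_samp, 0,
                                     spec$noise_sd),
                        nrow = length(mirna_names),
                        dimnames = list(mirna_names, clinical$sample_id))
  mir_base <- stats::rnorm(length(mirna_names), 3, 1)
  for (i in seq_along(mirna_names)) {
    lo <- eff(spec$mirna_loadings, mirna_names[i])
    mirna[i, ] <- mirna[i, ] + mir_base[i] + lo * h
  }

  truth <- rbind(
    data.frame(unit = targets, parameter = "hypoxia_loading",
               value = unname(spec$gene_loadings[targets]),
               stringsAsFactors = FALSE),
    data.frame(unit = targets, parameter = "de_shift",
               value = vapply(targets, function(g) eff(spec$de_shifts, g),
                              numeric(1L)), stringsAsFactors = FALSE),
    data.frame(unit = targets, parameter = "log_hr",
               value = vapply(targets, function(g) eff(spec$survival_log_hr, g),
                              numeric(1L)), stringsAsFactors = FALSE),
    data.frame(unit = names(spec$mirna_loadings), parameter = "mirna_loading",
               value = unname(spec$mirna_loadings), stringsAsFactors = FALSE))

  list(expression = expr, mirna = mirna, clinical = clinical,
       subtypes = subtypes,
       signatures = list(hypoxia = hyp_genes, stromal = str_genes,
                         immune = imm_genes),
       truth = truth)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the same TSV/GMT formats the readers consume: `expression.tsv`,
#' `mirna.tsv`, `clinical.tsv`, `subtypes.tsv`, `signatures.gmt`, and the
#' planted-effect sidecar `truth.tsv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_expression_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(cohort$subtypes, file.path(dir, "subtypes.tsv"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Generate NCI-60-style cell-line expression and drug-activity data
#'
#' Cell-line expression for the target genes plus planted linear gene-drug
#' couplings: `activity(d) = coupling * z(expr(gene_d)) + N(0, sigma^2)`,
#' null drugs pure noise, and missing cells inserted completely at random.
#'
#' @param n_cell_lines number of cell lines (default 60).
#' @param genes target gene identifiers.
#' @param couplings named list: drug id -> `list(gene =, coupling =, sigma =)`.
#'   Default plants one strong positive coupling (0.7, sigma 0.3) per the
#'   first target gene and a negative one on the second.
#' @param n_null_drugs unassociated drugs (default 20).
#' @param missing_rate fraction of activity cells masked MCAR (default 0.1,
#'   must be < 1).
#' @param seed integer RNG seed.
#' @return list with `expression` (genes x lines), `activity`
#'   (drugs x lines, with NAs), and `truth`.
#' @export
generate_drug_data <- function(n_cell_lines = 60L,
                               genes = c("VEGFA", "VEGFB", "VEGFC", "VEGFD", "PGF"),
                               couplings = NULL,
                               n_null_drugs = 20L,
                               missing_rate = 0.1,
                               seed = 1L) {
  if (missing_rate >= 1 || missing_rate < 0)
    stop("missing_rate must be in [0, 1)")
  set.seed(seed)
  if (is.null(couplings))
    couplings <- list(
      "drug-pos-1" = list(gene = genes[1L], coupling = 0.7, sigma = 0.3),
      "drug-neg-1" = list(gene = genes[min(2L, length(genes))],
                          coupling = -0.7, sigma = 0.3))
  lines <- sprintf("CL%02d", seq_len(n_cell_lines))
  expr <- base::matrix(stats::rnorm(length(genes) * n_cell_lines, 5, 1),
                       nrow = length(genes), dimnames = list(genes, lines))
  drugs <- c(names(couplings),
             if (n_null_drugs > 0) sprintf("drug-null-%02d", seq_len(n_null_drugs)))
  act <- base::matrix(stats::rnorm(length(drugs) * n_cell_lines),
                      nrow = length(drugs), dimnames = list(drugs, lines))
  for (d in names(couplings)) {
    cp <- couplings[[d]]
    if (!cp$gene %in% genes) stop("coupled gene not generated: ", cp$gene)
    z <- scale(expr[cp$gene, ])[, 1L]
    act[d, ] <- cp$coupling * z + stats::rnorm(n_cell_lines, 0, cp$sigma)
  }
  if (missing_rate > 0) {
    mask <- stats::runif(length(act)) < missing_rate
    act[mask] <- NA_real_
  }
  truth <- data.frame(
    drug_id = names(couplings),
    gene = vapply(couplings, function(cp) cp$gene, character(1L)),
    coupling = vapply(couplings, function(cp) cp$coupling, numeric(1L)),
    sigma = vapply(couplings, function(cp) cp$sigma, numeric(1L)),
    stringsAsFactors = FALSE)
  list(expression = expr, activity = act, truth = truth)
}
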