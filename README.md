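# panoxia

Pan-cancer association analysis of a target gene panel — by default the
five VEGF-family angiogenesis ligands (*VEGFA*, *VEGFB*, *VEGFC*, *VEGFD*,
*PGF*) — against tumor hypoxia, prognosis, immune subtype, tumor
microenvironment (TME) and drug response. It is written for computational
biologists who have genes-by-samples expression matrices (TCGA-style,
log-scale), clinical and immune-subtype tables, GMT gene signatures, and
optionally NCI-60-like drug-activity data, and who want the complete
multi-stage analysis as tested, reproducible library code.

## What it computes

**Per-sample signature scores.** Two scoring procedures drive the
analysis:

* A rank-weighted single-sample enrichment score. For sample *T* whose *n*
  genes are ordered by rank from highest (*n*) to lowest (1), and a
  signature *S* with *n*<sub>S</sub> genes,

  ES(S, T) = Σᵢ [ P_S^w(i) − P_nS(i) ],  with
  P_S^w(i) = Σ_{j∈S, j≤i} r_j^α / Σ_{j∈S} r_j^α and
  P_nS(i) = #{j∉S, j≤i} / (n − n_S),

  the running difference between the weighted empirical CDF of the
  signature genes and that of the rest, with α = 0.25. Stromal and immune
  signatures scored this way, plus their sum (the combined ESTIMATE-style
  score), quantify infiltration as an inverse proxy of tumor purity.
* A binary ±1 hypoxia score: the cohort is pooled across cancers, each
  signature gene's pooled median is computed, and a sample scores +1 per
  gene strictly above the median, −1 otherwise; the sum over signature
  genes is the sample's hypoxia score.

**Association stages**, each emitting statistic, p, BH-adjusted p and n:
tumor-vs-normal differential expression (exact Wilcoxon signed-rank on
patient-matched pairs, in cancers with more than five normals);
Spearman correlation of genes and of curated target miRNAs with hypoxia
scores, and of genes with stromal/immune/ESTIMATE scores, per cancer over
tumor samples; Kruskal–Wallis comparisons across immune subtypes C1–C6 and
across tumor stages I–IV; median-split survival analysis (Kaplan–Meier,
log-rank, univariate Cox with Efron ties); and KNN-imputed drug-activity
versus expression Pearson correlations across cell lines at p < 0.01.

A synthetic-cohort generator with planted effects (latent hypoxia axis,
tumor shifts, proportional hazards, subtype/stage shifts, gene–drug
couplings) plus a truth ledger makes every stage testable end to end
without any external download.

## Worked example

```r
library(panoxia)

co  <- generate_cohort(cohort_spec(seed = 7))   # 4 cancers, 120 tumors each
dir <- tempfile(); write_cohort(co, dir)

cfg <- list(inputs  = list(expression = file.path(dir, "expression.tsv"),
                           clinical   = file.path(dir, "clinical.tsv"),
                           mirna      = file.path(dir, "mirna.tsv"),
                           subtypes   = file.path(dir, "subtypes.tsv"),
                           signatures = file.path(dir, "signatures.gmt")),
            targets = list(mirna_target_map = vegf_mirna_target_map()),
            seed    = 7)
res <- run_full_analysis(cfg, file.path(dir, "out"))

subset(res$results$hypoxia_corr, grouping == "CA01")
#>    unit statistic  p_value    adj_p   n
#> 1 VEGFA    0.6227 3.11e-14 1.55e-13 120
#> 2 VEGFB   -0.0619 5.02e-01 5.02e-01 120
#> 3 VEGFC    0.1892 3.85e-02 4.81e-02 120
#> 4 VEGFD   -0.4538 1.93e-07 4.82e-07 120
#> 5   PGF    0.2850 1.60e-03 2.67e-03 120
```

Each row is one gene's Spearman correlation with the binary hypoxia score
over the 120 tumor samples of cancer `CA01`, BH-adjusted within that
cancer: the generator plants positive hypoxia couplings on VEGFA/PGF and a
negative one on VEGFD, and the pipeline recovers exactly those signs at
adjusted p < 0.05 while the null gene VEGFB stays flat. The survival stage
of the same run reports, per gene and cancer, the median-split log-rank p
and the Cox hazard ratio with its 95% interval — e.g. *PGF* in `CA01`
comes back with hr = 1.28 (1.07–1.53), cox_p = 0.006, matching its planted
adverse hazard. All stage tables are also written as TSVs next to a JSON
run manifest; rerunning with the same seed reproduces them byte for byte.

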