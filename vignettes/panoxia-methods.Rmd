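---
title: "Methods: signature scoring and pan-cancer association analysis with panoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring and pan-cancer association analysis with panoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panoxia)
```

# Scope and data model

panoxia implements a pan-cancer association workflow for a small panel of
target genes (by default the five VEGF-family angiogenesis ligands VEGFA,
VEGFB, VEGFC, VEGFD and PGF) against tumor hypoxia, prognosis, immune
subtype, tumor-microenvironment (TME) infiltration and drug response. The
substrate of every stage is a genes-by-samples matrix of log-scale
abundance (e.g. `log2(FPKM + 1)`), read from tab-separated files in the
dialect of UCSC-Xena-style exports (UTF-8, `NA` or empty cells missing).
Values are taken as provided; an optional `log2p1` flag applies
`log2(x + 1)` for raw linear-scale input. Gene identifiers are matched by
exact string equality after whitespace trimming: no alias resolution, so
scoring is deterministic and the user controls the identifier universe.

Clinical tables carry per-sample cancer type, tumor/normal status, a
patient link for matched pairs, overall-survival time and event, and tumor
stage (sub-stages IA, IIB, ... collapse to their major Roman numeral, since
the analyses are at four-stage resolution). Immune subtypes use the six
pan-cancer transcriptomic classes C1 (wound healing) through C6 (TGF-beta
dominant).

# Per-sample signature scoring

## Rank-weighted enrichment score

For one sample $T$ with $n$ genes, genes are ordered by expression from
highest (rank $n$) to lowest (rank 1). Ties are broken lexicographically by
gene identifier, the smaller identifier receiving the lower rank; the
ordering is therefore total, and scores are bit-identical across runs. For
a signature $S$ with $n_S$ genes present in the matrix, the enrichment
score is

$$ES(S, T) = \sum_{i=1}^{n} \left[ P_S^w(i) - P_{nS}(i) \right], \qquad
P_S^w(i) = \frac{\sum_{j \in S,\; j \le i} r_j^{\alpha}}
                {\sum_{j \in S} r_j^{\alpha}}, \qquad
P_{nS}(i) = \frac{\#\{j \notin S,\; j \le i\}}{n - n_S},$$

the running difference between the rank-weighted empirical CDF of the
signature genes and the unweighted empirical CDF of the rest. The exponent
$\alpha$ defaults to 0.25, down-weighting extreme ranks relative to
$\alpha = 1$; at $\alpha \to 0$ the weights become uniform and the score
reduces to a signed Kolmogorov-style sum. Because the score depends on
expression only through within-sample ranks, it is exactly invariant under
any strictly increasing per-sample transform — the property that makes
single-sample scores comparable across samples with different scales.
Signature genes absent from the matrix are dropped (never zero-filled,
which would corrupt ranks) and the size actually used is reported.

Stromal and immune infiltration are scored with this ES on user-supplied
stromal and immune signatures; their sum is the combined ESTIMATE-style
score used as an inverse proxy of tumor purity. The nonlinear
purity transform of the original ESTIMATE method is deliberately out of
scope: the composite here is the additive score only.

## Binary hypoxia score

The hypoxia score is a median-split vote. The cohort is pooled across
cancers; for each signature gene the pooled median is computed, and each
sample receives $+1$ for a value strictly above that median, $-1$
otherwise. The per-sample score is the sum over signature genes, an
integer in $[-n_{used}, n_{used}]$ with the parity of $n_{used}$. Values
exactly at the median count as $-1$ — "top 50%" is read as strictly above
the split point — and are reported in `ties_at_median` so the (rare, for
continuous data) ambiguity is auditable. Pooling before the split is what
makes scores comparable across cancers; correlations against the score are
then computed within each cancer's tumor samples. The scoring is per
sample: the per-cancer reading (scoring whole cancers) would not support
within-cancer correlation at all, so the per-sample reading is the one the
downstream analyses require.

# Statistical tests

All tests are two-sided; no one-sided claims are made anywhere.

* **Wilcoxon signed-rank** (tumor vs patient-matched normal). Zero
  differences are dropped with a logged count (Wilcoxon's original
  treatment, not Pratt's); absolute differences are ranked with average
  ranks for ties. The exact two-sided p-value — the probability over all
  $2^n$ sign patterns of a $|W|$ at least as large as observed — is
  computed by dynamic programming over the doubled (hence integer) rank
  sums whenever $n \le 25$, which remains valid under tied magnitudes; for
  larger $n$ a normal approximation with tie and continuity corrections is
  used. This component is implemented in full here because the standard
  implementation cannot produce exact p-values in the presence of ties.
  Only the paired test is offered: matched pairs are a precondition of the
  differential stage, and unpaired designs are outside its contract.
* **Kruskal–Wallis** (stage and immune-subtype comparisons) with the
  standard tie correction and the $\chi^2_{k-1}$ reference distribution.
* **Spearman** (hypoxia and TME correlations): Pearson correlation of
  average ranks with the t-approximation on $n - 2$ degrees of freedom.
* **Pearson** (drug–expression correlations across cell lines).
* **Benjamini–Hochberg** step-up adjustment. The adjustment family is, by
  default, the set of tests sharing one cancer type within one stage
  ("per_cancer"), switchable to a global family. Note that BH is not
  idempotent: re-adjusting adjusted values changes them, so adjusted
  p-values are computed exactly once per family.

# Survival analysis

Tumor samples of each cancer are split at the median expression of each
target gene; equal-to-median joins the high group, a deterministic rule
(for even cohorts the median is the midpoint of the central order
statistics, so the split is exact). The high/low groups are compared with
the log-rank test, and the gene's association with overall survival is
quantified by univariate Cox proportional-hazards regression with Efron
tie handling — tied event times are common at day resolution, and Efron's
approximation is less biased than Breslow's. The Cox covariate is
continuous expression by default; the binary median-split label is
available via `cox_covariate = "binary"`. Wald 95% intervals and p-values
are reported; fewer than ten events triggers a warning, and samples with
missing survival are dropped per-analysis with a logged count.

# Pipeline stages and eligibility rules

* Tumor-vs-normal comparisons run only in cancers with at least six normal
  samples ("more than five"), on patient-matched pairs, with BH across
  genes within each cancer and direction reported as mean(tumor) −
  mean(normal).
* Correlation stages (hypoxia, miRNA–hypoxia, TME) use all tumor samples
  of each cancer, never normals, and skip cancers with fewer than three
  usable samples.
* miRNA–target assignments are configuration, not computation: the shipped
  map (`vegf_mirna_target_map()`) lists literature-curated pairs for the
  VEGF panel, and any other mapping can be supplied.
* Subtype and stage comparisons require at least two groups with at least
  two samples each; absent groups are dropped from the test rather than
  failing, and per-group medians are reported for direction.
* `run_full_analysis()` executes every stage from a YAML or in-memory
  configuration, writes one TSV per stage plus a JSON manifest (inputs,
  parameters, seed, package version, per-stage failures), and contains no
  timestamps, so reruns with the same inputs and seed are byte-identical.
  Independent stages complete even when one fails. Numeric columns are
  serialized at 15 significant digits to keep reruns byte-stable.

# Drug-sensitivity analysis

Drug-activity matrices (drugs by cell lines, NCI-60-like) usually contain
missing values. Rows missing more than half their cells are dropped
(configurable `max_missing_frac = 0.5`); remaining gaps are filled by
k-nearest-neighbor imputation with $k = 10$: neighbors are the $k$ rows
closest in Euclidean distance on co-observed cells, scaled by the number
of co-observed cells so rows with different overlap are comparable, and a
missing cell takes the mean of the neighbors' observed values in that
column (falling back to the column mean if none is observed). Observed
cells are never altered, and complete matrices pass through unchanged.
Gene–drug Pearson correlations across the shared cell lines are then
filtered at unadjusted $p < 0.01$ and sorted by $|r|$; activity semantics
(e.g. $-\log_{10}$ GI50) are opaque — only linearity is assumed.

# Synthetic cohorts

The generator exists so that every stage — and every calibration and
recovery check — runs without external downloads. Per sample it draws a
latent hypoxia value $h \sim N(0,1)$ and latent stromal/immune factors
$u, v \sim N(0,1)$; expression of gene $g$ is

$$x_{gs} = \mu_g + \beta_g h_s + \gamma_g u_s + \delta_g v_s +
\Delta_g \mathbf{1}[\text{tumor}] + \text{subtype/stage shift} +
\varepsilon,\quad \varepsilon \sim N(0, \sigma^2),$$

with hypoxia-signature genes loading 1 on $h$ (so the binary score tracks
the axis), stromal/immune-signature genes loading 1 on $u$/$v$, and
$\sigma = 1$ by default. A gene with loading $\beta$ has population
correlation $\beta / \sqrt{\beta^2 + \sigma^2}$ with the latent axis —
about 0.62 for $\beta = 0.8$ — which is what the recovery checks measure
through the score. Overall survival is exponential with hazard
proportional to $\exp(\sum_g \theta_g z(x_{gs}))$, censored by an
independent exponential tuned to the requested censoring fraction (exact
under the null, approximate under covariate effects), and rounded to whole
days so that tied event times — the reason for Efron handling — actually
occur. Subtype and stage labels are uniform over their codes with additive
planted shifts.

Default effect sizes mirror the qualitative structure reported for the
VEGF panel in the angiogenesis literature: positive hypoxia coupling for
VEGFA/PGF and negative for VEGFD, tumor over-expression of all members
except VEGFD, modest adverse hazards for VEGFA/PGF, VEGFC coupling to
infiltration and to subtypes C3/C6. Where no quantitative value is
dictated by the emulated study design, magnitudes were fixed once at
values a bulk-RNA-seq analyst would call moderate (loadings 0.4–0.8 and
shifts 0.3–1.0 log-units against unit noise) and are not revisited;
an all-zero setting yields a global-null cohort. Drug data are generated
analogously: 60 cell lines, planted linear couplings (default 0.7 with
residual SD 0.3, giving population $r \approx 0.92$), and
missing-completely-at-random masking at rate 0.1.

The generator is deliberately idealized: Gaussian noise rather than
negative-binomial counts, no batch effects, no copy-number structure, and
independence across genes given the latent factors. Rank-based methods are
distribution-robust, so Gaussianity is not load-bearing for the
conclusions the tests draw; but passing tests demonstrate correctness of
the *procedures* under the stated model, not robustness to the full messiness
of real RNA-seq cohorts. All randomness flows from one Mersenne–Twister
seed in the `cohort_spec()` object; identical seeds give identical
cohorts.

# Calibration and recovery testing

The test suite checks the implementation along two independent routes:
definitional brute-force oracles (term-by-term ES summation, $2^n$
sign-pattern enumeration for the Wilcoxon p, rank-definition
Kruskal–Wallis H, step-up BH, direct partial-likelihood maximization for
Cox) frozen against worked values, and statistical calibration under the
generator. Null calibration uses 2,000 single-gene null cohorts per stage
— one test per BH family, so adjusted and raw p coincide and the nominal
5% level is the reference — with 120 tumor samples and 24 matched pairs
per cohort, sizes at which the chi-square and t approximations involved
are in their working range (the Kruskal–Wallis chi-square approximation
is known to sit slightly below nominal, around 4.5%, at moderate group
sizes; the acceptance band accommodates this). Log-rank calibration uses
5,000 two-group simulations of 30 + 30 exponential survivors. Recovery
checks use true hazard ratio 2 at $n = 1000$ (200 replicates), hypoxia
loadings $|\beta| \ge 0.6$ at 200 samples per cancer, and the 0.7 drug
coupling at 60 cell lines. These problem sizes are the package's own
calibration conditions and are fixed in the tests.

Monotone-separation draws (a binary covariate perfectly ordered with the
event ranking) leave the Cox partial likelihood without an interior
maximum; the oracle comparison skips such non-identified instances.

# Known limitations

* The ESTIMATE composite is the additive stromal + immune score; no
  purity fraction is produced.
* Only univariate Cox is offered — no stratification, multivariable
  adjustment, time-dependent covariates or competing risks.
* The Kruskal–Wallis p-value is asymptotic; no permutation or exact
  variant is provided.
* The miRNA–target map is user curation; the package performs no target
  prediction.
* Signature content is entirely user-supplied (GMT); the package ships no
  gene lists beyond the synthetic generator's labels.
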