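---
title: "EMT scoring and PD-L1 stratified biomarker analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMT scoring and PD-L1 stratified biomarker analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtici)
```

# The scientific problem

Epithelial-mesenchymal transition (EMT) is a phenotypic shift of carcinoma
cells from an epithelial state (E-cadherin-high, tight-junction-intact)
toward a mesenchymal state (vimentin/N-cadherin-high, motile), and it is
associated with resistance to therapy. In non-small-cell lung cancer treated
with immune checkpoint inhibitors (ICIs), a mesenchymal tumor phenotype has
been linked to poor response and shorter progression-free survival — but
specifically among tumors with high PD-L1 expression. `emtici` implements
the statistical machinery needed to test that kind of claim on a cohort:
per-sample EMT scoring from bulk expression, immune signature scoring,
PD-L1 x EMT stratification, response-group comparisons, correlations,
survival analysis, and ROC-based cutpoint selection for IHC H-scores, plus
a synthetic cohort generator so the whole pipeline is testable without
access to patient-level data.

# The EMT score

For a single sample, let $E$ be the expression values of the matched
epithelial signature genes and $M$ those of the mesenchymal genes, with
empirical cumulative distribution functions (right-continuous, ties counted
with $\le$)

$$F_E(x) = \frac{\#\{e \in E : e \le x\}}{|E|}, \qquad
  F_M(x) = \frac{\#\{m \in M : m \le x\}}{|M|}.$$

On the pooled support define the one-sided two-sample Kolmogorov-Smirnov
statistics

$$D^+ = \max_x \left(F_E(x) - F_M(x)\right), \qquad
  D^- = \max_x \left(F_M(x) - F_E(x)\right).$$

The EMT score is $+D^+$ if $D^+ > D^-$ and $-D^-$ if $D^- > D^+$: positive
when the mesenchymal expression distribution sits above the epithelial one
(a mesenchymal-shifted sample), negative for an epithelial-shifted sample.
The score lives in $[-1, 1]$, reaches $\pm 1$ exactly when the two value
sets are completely separated, and — because it depends on the data only
through within-sample ranks — is invariant to any strictly increasing
transform of a sample's expression vector. That rank invariance is why the
score is insensitive to the expression scale convention (log2 of a
normalized quantity plus one is assumed, but any monotone re-expression
gives the same score).

Numerical choices that the definition leaves open:

* **Tie between $D^+$ and $D^-$** (both maxima equal and positive, e.g.
  two distributions that cross symmetrically). The sign is taken from the
  comparison of mean pooled ranks of the two arms, and the score is 0 if
  those are also equal. This is deterministic, symmetric under swapping the
  arms, and reduces to 0 for identical distributions.
* **Gene coverage.** A sample is scored only if at least `min_genes`
  (default 10) genes per arm are matched in the matrix and finite;
  otherwise the result row is flagged `valid = FALSE` with an `NA` score
  rather than a number computed from a degenerate ECDF.
* **Missing values** are dropped per sample before scoring so a single
  non-finite entry cannot poison a sample's score.

# Signature scores

Immune-context scores (cytotoxic T lymphocyte, Treg, M1 and M2 macrophage
signatures) are defined as the mean over signature genes of the per-gene
z-score of log2 fold-change. On log2-scale data the fold-change against a
cohort reference is a per-gene subtraction, and the subsequent z-scoring
(sample sd, $n-1$ denominator) removes each gene's location and scale
entirely. Consequently the choice of fold-change reference — cohort mean,
cohort median, or none — is mathematically immaterial; the package defaults
to the cohort mean and the test suite asserts the invariance to $10^{-12}$.
Zero-variance genes cannot be z-scored and are excluded from the signature
mean with a warning; a signature needs `min_genes` (default 3) usable genes
to be scored. Each score column has cohort mean zero by construction, so
scores are relative contrasts within the analyzed cohort, not absolute
abundances.

# Stratification, comparisons, cutpoints

* **Median splits.** PD-L1 expression and the EMT score are split at the
  cohort median; values strictly above the median are "high", values equal
  to the median go to "low". The tie policy is a fixed convention (the
  analysis it mirrors specifies only "according to the median").
* **TPS split.** For IHC cohorts PD-L1-high is a tumor proportion score
  $\ge 1$, boundary inclusive.
* **Group comparisons** use the unpaired two-tailed Welch t-test (default)
  or the Mann-Whitney test; correlations use tie-corrected Spearman rank
  correlation with the two-sided t approximation on $n-2$ degrees of
  freedom. No multiple-testing correction is applied anywhere: raw p-values
  are reported and significance is read at 0.05, matching the analysis
  style the package reproduces.
* **ROC cutpoints** for H-scores enumerate candidate thresholds at the
  midpoints of consecutive sorted unique marker values plus sentinels below
  the minimum and above the maximum, call a sample positive when marker
  $\ge$ threshold, and select the threshold minimizing the Euclidean
  distance $\sqrt{(1-\text{sens})^2 + (1-\text{spec})^2}$ to the ideal
  corner of the ROC plane. Ties are broken by the larger Youden index, then
  the smaller threshold. For markers where *low* values predict the event
  (E-cadherin), the marker is negated internally and the threshold mapped
  back, so one convention serves all markers. The outcome the ROC
  discriminates is configurable and defaults to progression (PD vs
  non-PD) — the underlying study does not state which outcome was used, so
  this default is declared rather than inferred.

# Survival analysis

Progression-free and overall survival are analyzed with the Kaplan-Meier
product-limit estimator and the two-group log-rank (Mantel-Haenszel) test,
delegated to the `survival` package with fixed conventions: events are
processed before censorings at tied times, contrasts are pairwise
(two-group only), and the chi-square has 1 degree of freedom. The headline
contrasts are EMT-high vs EMT-low *within* the PD-L1-high stratum and
separately within PD-L1-low, alongside the marginal PD-L1 and EMT splits.
Degenerate contrasts (an empty group or no events) are skipped with a
warning instead of erroring, so a report is always produced. The test suite
pins the estimator with a hand-derived 4-patient example
($O_A = 2$, $E_A = 5/6$, $V = 17/36$, $\chi^2 = 49/17 \approx 2.882$) and
calibrates the test's type-I error under the null to $[0.04, 0.06]$ at
2000 seeded replicates.

# Bundled gene-set fixtures

The published EMT signatures (315 genes for tumor tissue: 145 epithelial +
170 mesenchymal; 218 genes for cell lines: 170 + 48) and the immune gene
sets live in a supplement that is not redistributable here. The bundled GMT
files are therefore **synthetic placeholders** (`*_synthetic.gmt`, flagged
in their description fields): they reproduce the exact arm sizes, are
seeded with canonical epithelial/mesenchymal and immune marker genes
(CDH1, EPCAM, keratins; VIM, ZEB1/2, SNAI1/2, TWIST1/2, collagens; GZMB,
FOXP3, CD163, ...) and are padded with clearly synthetic `SYN*` symbols.
Analyses of real cohorts should replace them with the transcribed published
lists via `load_emt_signature()` on a user GMT; everything in the package
treats the gene lists as data, not logic.

# The synthetic cohort generator

The generator encodes, as ground truth, the minimal statistical structure
under which the signed-KS score is a consistent estimator of a mesenchymal
shift and under which the stratum-restricted clinical claim is falsifiable:

* one latent EMT axis $e_i \sim N(0,1)$ per patient;
* epithelial genes $x = \mu_g - \beta e_i + \varepsilon$ and mesenchymal
  genes $x = \mu_g + \beta e_i + \varepsilon$, with baselines
  $\mu_g \sim N(5, 1)$ on the log2 scale (realistic magnitudes, irrelevant
  to rank-based scoring), loading $\beta = 1$ and noise sd 1;
* a latent PD-L1 variable correlated with $e_i$ at $\rho_p = 0.2$, stored
  both as the `pdl1_expr` column and as a `CD274` expression row;
  PD-L1-high is the upper median half;
* immune signature genes loaded on $e_i$ only within PD-L1-high patients
  ($-\kappa$ for CTL, $+\kappa$ for Treg and M2, unloaded for M1;
  $\kappa = 0.8$);
* response PD with probability $\mathrm{logit}^{-1}(\gamma_r e_i)$ within
  PD-L1-high and $1/2$ otherwise ($\gamma_r = 1$), else PR;
* exponential PFS with hazard multiplied by $e^{\gamma_h e_i}$ within
  PD-L1-high ($\gamma_h = 0.8$), baseline scale 6 months, OS with twice
  that scale; independent exponential censoring with rate
  $\frac{c}{1-c}$ times the baseline event rate, so a fraction $\approx c$
  (default 0.2) of baseline follow-up is censored.

Defaults mirror the emulated study's dimensions (234 RNA-seq patients, 90
IHC patients, 145/170 signature arms, four 20-gene immune sets, 2000
background genes). Effect sizes in the real cohort are unknown (the figures
print no reusable numbers), so $\beta, \gamma_r, \gamma_h, \kappa$ were
chosen once for detectability at the study's sample sizes and are not
revisited; they are parameters of the generator, not estimates. The IHC
generator draws integer H-scores in $[0, 300]$ centred at 150 with loading
60 per latent unit and residual sd 40 (E-cadherin negatively loaded), and a
zero-inflated TPS (35% exact zeros).

What the generator deliberately does **not** emulate: RNA-seq count noise
(negative binomial dispersion), batch effects, tumor purity, correlated
gene-gene structure beyond the single latent axis, and non-proportional
hazards. Passing recovery tests therefore demonstrate that the pipeline's
statistics recover the structure they claim to measure — not that the
biological effect sizes of any real cohort are reproduced.

# Problem sizes used in validation

The test and acceptance suites run: 1000 random value-pairs (sizes 1-50,
with ties) against a brute-force KS oracle; 500 random instances
($n \le 50$) against an exhaustive cutpoint search; 2000 null replicates at
$n = 100$ for log-rank calibration; and 100 synthetic cohorts at the full
default size ($n = 234$) for the recovery suite, where the PD-L1-high
contrasts (PR-vs-PD score difference; EMT-split log-rank) must reject at
$\alpha = 0.05$ in at least 80% of seeds while the PD-L1-low contrasts stay
at the nominal rate ($\le 10\%$). These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands.

# Known limitations

* Gene matching is exact, case-sensitive symbol matching; alias resolution
  is out of scope and should be handled upstream.
* The KS score is a score, not a test: no p-value is attached to it, and
  GSEA-style weighted enrichment is intentionally not implemented.
* Two-group log-rank only; k-group tests and Cox models are out of scope.
* The bundled signatures are placeholders (above); results on real data are
  only meaningful with the published gene lists supplied by the user.
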