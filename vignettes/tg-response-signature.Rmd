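---
title: "Methods: the TG-response gene-expression signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TG-response gene-expression signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgpredict)
```

`tgpredict` discovers and evaluates peripheral-blood gene signatures that
predict whether a rheumatoid-arthritis patient will respond (reach ACR20)
to Tripterysium glycosides tablets.  This vignette documents the models,
the tunable parameters, the numerical conventions, and the design
decisions taken where the underlying methodology left choices open.

## The moderated differential-expression screen

Small two-group cohorts (six responders, six non-responders is the typical
discovery design) make per-gene variance estimates unstable.  The random
variance model treats gene precisions as exchangeable draws from a Gamma
distribution with shape $a$ and scale $b$; under that prior the scaled
sample variances satisfy $a\,b\,s_g^2 \sim F(m, 2a)$ with $m = n_1+n_2-2$.
`fit_rvm_prior()` maximises this F likelihood (method-of-moments start,
Nelder–Mead on log-parameters; failure falls back to the moment estimates
with a warning).  The moderated variance

$$\tilde\sigma_g^2 = \frac{m\,s_g^2 + 2/b}{m + 2a}$$

is a shrinkage of $s_g^2$ towards the prior mode, and the moderated
$t = \bar x_{1g}-\bar x_{2g} \,/\, \sqrt{\tilde\sigma_g^2 (1/n_1+1/n_2)}$
is referred to $t_{m+2a}$.  As $a \to 0$ with $2/b \to 0$ the test reduces
to the pooled Student $t$ (asserted to $10^{-6}$ in the tests).  Genes with
zero pooled variance get $t = 0$, $p = 1$ and a flag, never dropped, so row
alignment is preserved.

Expression is assumed **log2-scale** on input (the scale of the usual
normalised microarray matrix; `expression_matrix(..., linear_input = TRUE)`
transforms linear data and rejects non-positive values).  Fold change is
defined as $2^{\,\bar x_\text{resp} - \bar x_\text{non}}$ — the power of
the log2 mean difference, not the ratio of linear means; the two differ and
the convention must be declared, so it is.

The default screen keeps $|\log_2 FC| > 0.5$ **and** $p < 0.05$, both
strict inequalities (a gene at exactly 0.5 is excluded).  Reported
descriptions of this screen vary (a 1.2-fold wording also circulates); the
0.5/0.05 pair is the default here and both are ordinary parameters of
`screen_degs()`.  No multiple-testing correction is applied at this stage,
matching the workflow this package implements; the enrichment module is
where corrected p-values appear.

## Network-topology candidate selection

Interaction edges (STRING-dialect combined scores, integers in 150–999)
are first filtered to those **strictly above the median score**; the
network is then the subgraph induced by the screened DEGs (undirected,
deduplicated, isolated genes dropped).  The filter-then-subset order is a
choice — the alternative (subset first) changes the median — and is fixed
here because the score distribution of the full table, not of the DEG
pairs, is what the evidence threshold describes.

Three centralities are computed per node: degree (edge count; a
score-weighted variant sits behind `weighted_degree = TRUE`, since printed
degree values in the reference table are small integers consistent with
counts), unnormalised shortest-path betweenness, and closeness defined per
connected component as $(n_c-1)/\sum d$.  Closeness normalisations differ
across tools and the published table's scale matches none of the standard
ones; because the selection rule only compares against the **median**,
which is invariant to monotone rescaling, only ranks matter and the
per-component definition is used.  *Major genes* exceed all three medians
simultaneously (strict, so ties at the median are excluded); *candidates*
are major genes with $p < 0.05$ and fold change $> 1.5$ or $< 1/1.5$.
Applying this rule to the shipped 16-gene table (`tg_major_genes()`)
returns exactly the six published biomarkers.

## Over-representation analysis

`enrich()` is a local replacement for web-service annotation tools: plain
hypergeometric upper-tail p-values per gene set (no EASE-style score
modification), corrected both by Bonferroni and Benjamini–Hochberg, with
significance requiring **both** corrected values below α = 0.05.  The
background defaults to the genes of the expression matrix, the standard
microarray practice; the universe an external service would have used is
unknowable and not guessed.

## The PLS score and its threshold

Candidate-gene expression is standardised per gene on training statistics;
the response is coded +1/−1 and centred (the symmetric coding makes the
weight-sign property exact: each first-component weight carries the sign of
that gene's covariance with response).  The first component's weight vector
is $w \propto X^\top y$ normalised to unit length — the closed-form
maximiser of $\mathrm{cov}^2(Xw, y)$ — and the patient score is
$\sum_i L_{p_i} W_{p_i}$ on standardised expression $L$.  One component is
the default (six features, a dozen training samples); more components use
NIPALS deflation and store the aggregated coefficients.

The threshold $T$ maximises Youden's $J$ over the $n+1$ cutoff positions
around the sorted distinct training scores (one below the minimum, the
midpoints, one above the maximum).  "ROC-optimal cutoff" phrasings are
sometimes circular (AUC itself is cutoff-free); maximising $J$ is the
standard concrete reading and is what is implemented.  Ties break towards
higher accuracy, then towards the lower cutoff — fully deterministic.  If
no cutoff beats $J = 0$ the lowest candidate is returned with a
`degenerate` flag.  Models serialise to JSON at 17 significant digits so
round-trips are bit-exact.

## Evaluation

Sensitivity, specificity and accuracy follow the usual confusion-matrix
formulas, with 0/0 ratios reported as `NaN` plus a flag.  The ROC curve
sweeps distinct cutoffs with ties grouped (half-credit), and its
trapezoidal AUC equals the Mann–Whitney statistic $U/(n_1 n_2)$ — the
tests assert this on random tied instances.

Cross-validation is **repeated stratified k-fold** with defaults
$5 \times 5$: "5-fold, five times" can mean either the five folds of one
split or five repeats, so both are reported (per fold, per repeat,
overall).  Every fold refits the model *and* the per-gene standardisation
on its training part only — no information from the held-out fold leaks
into centring, scaling or the threshold.  Correlated-AUC comparisons use
DeLong's test (the field default where no method is named); comparing a
score vector with itself, or two perfectly separating vectors, returns
$p = 1$ by convention since the DeLong variance vanishes.  Group
comparisons of single-gene expression use classic one-way ANOVA
(`oneway.test` with equal variances; with two groups $F = t^2$).

## qPCR quantification and cross-platform validation

`relative_quantify()` implements $2^{-\Delta\Delta C_t}$ with amplification
efficiency fixed at 2: replicate $C_t$ values are averaged per sample ×
gene (the pair-replicates-then-difference order is available as
`aggregate = "per_replicate"` and agrees on balanced tables), ΔCt
subtracts the reference gene, and ΔΔCt subtracts the calibrator — by
default the **non-responder group mean** ΔCt, so reported quantities are
fold changes relative to that group and the calibrator group's geometric
mean RQ is exactly 1.  The calibrator is overridable (a named sample gives
classic single-calibrator ΔΔCt).  Two reference genes (GAPDH, RPS18
defaults) are handled as two separate single-reference analyses; no
geometric-mean combination is applied because the underlying workflow
normalises "respectively", never jointly.

`qpcr_to_expression()` returns $\log_2 RQ = -\Delta\Delta C_t$ as an
`expr_matrix`.  Those values are centred on the calibrator group, while a
microarray-trained model stores centring constants on the array's absolute
log2-intensity scale; applying them across platforms is meaningless.
`run_validation(..., restandardize = TRUE)` therefore re-centres and
re-scales each signature gene on the validation cohort — weights and
threshold stay exactly as trained — and is the intended mode for qPCR
validation cohorts.  The default (`FALSE`) keeps the strict scoring
contract for same-platform data.

## The synthetic-cohort generator

`sim_config()` defaults encode the study conditions the pipeline is built
for: 2000 genes; 6 + 6 discovery and 15 + 16 validation samples; 5% of
genes differentially expressed with $|\log_2 FC| = 2$ and a balanced
up/down split (mirroring the roughly half-up, half-down splits typical of
responder screens); precisions from Gamma(shape 3, scale 1) — mean gene SD
≈ 0.7 log2 units, a realistic microarray residual; an Erdős–Rényi
background graph of mean degree 2 over which 6% of planted genes become
hubs with 20 extra spokes towards other planted genes, scored from the
upper half of the 150–999 range so they survive the median filter; and
triplicate qPCR $C_t$ values with 0.2-cycle replicate noise, two
group-independent reference genes, and a per-sample offset that ΔCt
normalisation must cancel.  All streams derive from `seed` (network and
qPCR stages use fixed offsets), so identical configurations are
bit-reproducible.

What the generator does **not** emulate: probe-level effects,
normalisation artefacts, batch structure, missing data, correlated
co-expression beyond the planted hubs, or qPCR efficiency differences.
Passing tests therefore demonstrate that the pipeline recovers the signal
structure it assumes — planted DE genes, planted hubs, calibrated null
behaviour — not that it is robust to real-data pathologies outside that
model.

## Problem sizes in the test-suite experiments

The statistical tests run at deliberately modest sizes chosen to make
Monte-Carlo error negligible relative to the asserted tolerances: 20 null
cohorts of 2000 genes for the type-I-error band (99% binomial interval
around 0.05 on 40,000 p-values); 10,000 variances for prior recovery
(±15%); 20 seeded end-to-end pipelines at 8 + 8 for hub recovery (≥ 80%);
20 discovery→validation experiments at the 6 + 6 / 15 + 16 cohort sizes;
and oracle comparisons (exhaustive betweenness enumeration at n ≤ 12,
10⁵-vector covariance search for the PLS weight, exhaustive cutoff scans)
on small instances where brute force is exact.

## Known limitations

The published weights and threshold shipped in `tg_signature_model()` are
a scoring fixture: reproducing them numerically would require the original
discovery cohort's normalised matrix and unstated preprocessing, so no
attempt is made.  The closeness values of the published topology table are
likewise not reproduced, only the rank-based selection they feed.  DEG
p-values are uncorrected by design; the enrichment module is a plain
hypergeometric, not an EASE score; and with n = 6 + 6 any classifier —
including this one — is a hypothesis generator, not a validated clinical
tool.
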