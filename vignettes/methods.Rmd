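---
title: "metaMiner: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaMiner: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaMiner)
```

metaMiner takes a metabolomics peak table — samples × variables of
integrated ion intensities — through preprocessing, annotation, variable
expansion, differential and marker statistics, generalized correlation, and
pathway topology/enrichment. This vignette documents the statistical models,
the conventions chosen where several are defensible, and what the synthetic
data generator does and does not emulate.

## The data model

A `PeakSet` extends `SummarizedExperiment`: the `"intensity"` assay stores
variables × samples, `colData` carries the sample metadata (group label,
injection order, QC flag, numeric confounders) and `rowData` the variable
metadata (m/z in Dalton, retention time, centroided spectrum, ratio-variable
flag). `intensities()` returns the matrix in the samples × variables
orientation used by peak-table files. Intensities are non-negative or
missing; a provenance list records the processing already applied — in
particular a log-transform flag, so fold changes are always reported on the
raw concentration scale.

## Preprocessing

**Outlier replacement.** Per variable, the mean and the sample SD (n − 1
divisor) are computed once over the non-missing values; points with
|x − mean| > 3 SD are replaced by the maximum of the non-flagged values.
The rule is deliberately single-pass and literal — including the quirk that
a *low* outlier is replaced by a maximum; `side = "high"` restricts
replacement to the upper tail. Because replacement shrinks the SD, a second
pass may flag new points; the operation is documented as non-idempotent and
the tests only require that a second pass replaces no more than the first.
Variables with fewer than three observations are skipped.

**Imputation.** Three strategies with different missingness assumptions:
the per-variable observed *minimum* (missing-not-at-random, detection
limited); *KNN* (missing at random) — donors weighted uniformly, Euclidean
distance over the z-scored variables observed in both samples, rescaled by
the number of shared variables, `k = 10` capped at the available donors;
and *QRILC* for left-censored data: per variable, a normal distribution is
estimated by regressing the observed order statistics on standard-normal
quantiles, using only the upper 75 % of the observed distribution where
censoring distorts least, with plotting positions shifted by the observed
missing fraction; imputed values are drawn from that normal truncated to
(0, observed minimum]. The truncation below zero keeps draws on the
intensity scale; QRILC is intended for raw (not log) intensities here.
Draws are reproducible given `seed`.

**Normalization.** *Total intensity*: each sample is divided by its row sum
and rescaled by the median row sum — the rescale keeps values on a familiar
intensity scale while making row sums equal; whether to rescale at all is a
free choice, and the median total is used because it leaves a "typical"
sample nearly unchanged. *Internal standard*: division by the named IS
variable, which must be positive in every sample. *QC-RLSC*: per variable,
a LOESS curve (degree 1, span 0.75 — a deliberately stiff smoother, since
drift is slow relative to the injection sequence) is fitted to the QC
intensities against injection order; every sample is divided by the curve
value at its own order (times the QC median, preserving scale). At least 5
QC injections are required; the curve is clamped to its edge values outside
the QC range rather than extrapolated.

**Transforms.** Natural log with a half-minimum pseudo-count applied only
to zeros, per variable; z-score with constant variables mapped to zero
under a warning.

## Annotation conventions

ppm error is `(observed − reference) / reference × 1e6`, asymmetric by
definition; the implementation's convention is asserted in tests. Mass
windows are inclusive (≤ tol); the retention-time gate and the spectral
similarity threshold are strict (<  and > respectively), matching the usual
reporting of "similarity > 0.7, RT tolerance < 0.3". Candidates are ranked
by |ppm| (ties: |RT error|, then compound id) or by similarity (ties:
compound id), so output is a deterministic total order. GC-MS similarity is
the cosine of √-intensity vectors on unit-Dalton bins (`round(mz)`); the
square root tempers the dominance of base peaks. Adducts are handled as a
configurable list of mass shifts applied to the neutral library mass before
matching; no isotope-pattern or MS/MS scoring is attempted.

## Ratio variables

For each reaction pair whose substrate and product are both measured, the
per-sample product/substrate intensity ratio is appended as
`"product/substrate"`. Zero or missing substrate gives a missing ratio.
When several variables carry the same compound annotation the one with the
highest median intensity represents it — deterministic and robust, and
recorded in the provenance table. A reversible pair yields one ratio as
listed (`both_directions = TRUE` for both); expansion is intended after
imputation/normalization, and because a within-sample ratio cancels any
per-sample scale factor, expanding before or after total-intensity
normalization is provably equivalent (tested as an algebraic property).
The interpretation of ratios as proxies of enzyme activity is left to the
analyst; nothing quantitative is derived from it.

## Univariate statistics

The default two-group test is Welch's t — "Student's t" without the
equal-variance assumption, the safer default for intensity data; the pooled
test is available (`t_test`). FDR (Benjamini–Hochberg) is the default
correction, appropriate when several metabolites are expected to pass;
Bonferroni and Holm are provided. All three delegate to `stats::p.adjust`
and are verified in the tests against hand-coded textbook step procedures.
The joint screen `p < 0.05 ∧ VIP > 1` uses strict inequalities on both
sides.

## PCA, PLS-DA, OPLS-DA

PCA is the SVD of the column-centered (and by default unit-variance scaled,
the metabolomics convention for peak tables of widely differing intensity)
matrix; the sign convention (largest-magnitude loading positive) makes
output deterministic. PLS-DA uses NIPALS against the centered group dummy
matrix (tolerance 1e-10, max 500 iterations, initialized from the largest-
variance response column). OPLS-DA (two groups) removes the requested
number of class-orthogonal components — weight `w ∝ X'y`, orthogonal weight
the component of the loading orthogonal to `w` — and fits a single
predictive component on the filtered matrix.

VIP uses the predictive weights and per-component explained response
variance, normalised so mean VIP² = 1 for a single response; this is the
quantity the conventional VIP > 1 cutoff assumes, and it is cross-checked
in the tests against an independent PLS implementation. Q² is estimated by
7-fold cross-validation stratified by group; the permutation test refits
under label shuffles and reports the add-one estimator
`(1 + #{Q²perm ≥ Q²}) / (1 + B)`, which cannot be zero. Q² was chosen as
the permutation statistic (over R²) because it is the quantity that
collapses under label exchange; a flag is not offered — users wanting R²
can read it from the model object.

## Marker screening

RF importance is the permutation (mean decrease in accuracy) measure, not
Gini: it is comparable across variables, and it is what the shadow-feature
test requires. The SVM ranking uses |w| under the linear kernel; under
nonlinear kernels a recursive elimination based on held-out-fold
permutation importance drops the weakest fifth per round (a pragmatic
middle ground between the O(p²) leave-one-out criterion and a single
ranking pass). Fixed defaults: cost 1, γ = 1/p, mtry = √p.

Boruta is implemented natively: per iteration every candidate gets a
row-permuted shadow copy, a forest is fitted on candidates plus shadows,
and a candidate scores a hit when its importance exceeds the maximum shadow
importance. Two-sided binomial tests at α = 0.01, Bonferroni-corrected
across candidates, promote to confirmed / demote to rejected; rejected
variables leave the forest, undecided ones end tentative. A single
iteration can never reach significance, so `max_iter = 1` leaves everything
tentative by construction.

The collaborative screen resamples stratified bootstraps; per classifier
(one-component PLS-DA, RF, linear SVM) a variable succeeds when permuting
it lowers out-of-bag accuracy, and a one-sided binomial test at α = 0.05
across bootstraps assigns tier A. The final set is tier A in ≥ 1
classifier. Published tiered-signature algorithms are more elaborate
(nested tiers, recursive restriction); this module implements the stated
contract — collaborative screening with resampled significance — and keeps
the two-tier mapping as a documented simplification.

## Generalized correlation

The metabolome–microbiome procedure is a concrete two-channel design:
taxa are CLR-transformed (zeros → half the minimum positive value),
metabolites are log-transformed by default, both are residualized on the
confounders by linear regression, then a *linear* channel (Pearson on
residuals) competes with a *nonlinear* channel (distance correlation with
a 199-permutation p, seeded; 199 gives p-resolution 0.005). The channel
with the smaller p names the pair's type and supplies r and p; q is FDR
across pairs. Distance correlation was chosen over MIC for its clean
U-statistic definition and an exact O(n²) oracle; the arbitration rule
(compare channel p-values, ties to linear) is this package's own and is
isolated in one function. Partial Spearman residualizes ranks on ranked
confounders, the textbook construction.

## Pathway topology and enrichment

Enrichment is the one-sided upper-tail hypergeometric probability with the
species' library universe as the population — the convention of the
established pathway-analysis web tools; `universe = "measured"` restricts
to measured compounds.
Impact is Σ centrality(hits) / Σ centrality(all nodes) ∈ [0, 1]; an
edgeless graph falls back to the hit fraction with a warning. Degree and
closeness respect edge direction after expanding reversible reactions to
both directions; betweenness (normalized by (n−1)(n−2)/2, the "relative"
convention) and eigenvector use the undirected expansion, because directed
eigenvector centrality is ill-defined on reaction graphs that are not
strongly connected — this is the package's key topological convention. A
reversible reaction is a single undirected connection, never a parallel
edge. Eigenvector centrality is computed by power iteration on A + I
(shifting prevents the ±λ oscillation of bipartite graphs), tolerance
1e-13, scaled to maximum 1; closeness sums distances to reachable nodes
only and is 0 for isolated nodes. Enrichment never depends on the
centrality algorithm — switching algorithms changes impact only, which the
tests assert bit-exactly.

## Clustering, ROC, power, Venn, regression

Ward means `ward.D2` (squared-Euclidean updates); mcquitty/median/centroid
are WPGMA/WPGMC/UPGMC. Minkowski's exponent defaults to 3 (distinct from
both Euclidean and Manhattan); "binary" is Jaccard on the nonzero pattern;
correlation distance is 1 − r and is exempt from the triangle-inequality
property the other metrics satisfy. Median and centroid linkage can
produce inversions (non-monotone heights); they are provided for
completeness. AUC uses the midrank (Mann–Whitney) formulation, exactly the
concordant-pair count under ties; the reported cutoff maximizes Youden's
J. Power calculations use the exact noncentral t/F (normal for the
arcsine-transformed two-proportion case) with *both* rejection tails, so
power tends to α as the effect vanishes; solved sample sizes are rounded
up and re-verified. Venn regions are brute-force membership counts (2 to 6
sets). OLS refuses rank-deficient designs, naming the collinear columns.

## The synthetic-data generator

`simulatePeakTable()` draws log-normal intensities (per-variable mean log
intensity uniform on log(1e4)–log(1e6), biological SD 0.2–0.6 log units —
typical magnitudes for integrated MS peak areas), plants group shifts of
`effect_size` SDs with alternating sign on the first `n_informative`
variables, applies multiplicative injection-order drift, inserts pooled-QC
samples (analytical SD 0.05 log units) every `qc_every` injections, and
censors either the low tail of each variable (making QRILC's assumption
true by construction) or at random. The default design — 30 samples per
group, 200 variables, 10 informative at 1.5 SD, 5 % missingness — is the
reference condition for the recovery checks in the tests and the
acceptance script. `simulateCoupledMicrobiome()` adds a compositional taxa
table with planted linear (slope 1 on the z scale, noise SD 0.5),
quadratic (Pearson-silent) and confounder-driven couplings;
`simulatePathwayLibrary()` builds connected random pathway graphs over a
shared compound pool whose edges are exactly the reaction-pair database.

What the generator does *not* emulate: correlated variable blocks,
batch effects beyond smooth drift, heavy-tailed analytical noise,
isotope/adduct degeneracy among variables, zero-inflated taxa counts, or
realistic pathway topology (KEGG maps are not random graphs). Passing the
recovery and calibration tests therefore demonstrates correctness of the
algorithms under their stated assumptions, not performance on any real
cohort.

## Problem sizes and numerical choices

The test-suite and acceptance designs (60 × 200 recovery tables, 2,000
null variables, 199-permutation nonlinear p, 20-seed replication) were
chosen as the smallest sizes at which the binomial acceptance bounds are
meaningful. NIPALS tolerance 1e-10; power-iteration tolerance 1e-13;
round-trip serialisation keeps 15 significant digits; all stochastic
steps take an explicit integer seed and are bit-reproducible.

## Known limitations

Raw LC/GC-MS data processing (peak picking, deconvolution) is out of
scope — the peak table is the entry point. OPLS-DA supports two groups and
a single response; multi-block and time-series models are not offered.
The SVM screen is two-group only (no one-vs-rest). The generalized
correlation's channel arbitration is a pragmatic stand-in for more
elaborate published procedures and is flagged as such. No pathway content
ships with the package; libraries are read from the documented text format
or simulated.
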