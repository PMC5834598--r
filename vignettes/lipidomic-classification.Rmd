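---
title: "Chemometric classification of direct-infusion lipidomic spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric classification of direct-infusion lipidomic spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoclass)
```

## The problem

Direct-infusion ESI mass spectrometry of plasma lipid extracts produces one
centroided spectrum per patient: a few hundred to a few thousand (m/z,
intensity) pairs on a mass axis that differs from sample to sample. The
clinical question addressed here is two-class: does a plasma sample come
from a woman negative for intraepithelial lesion or malignancy (NILM) or
from one carrying a squamous intraepithelial lesion (SIL, the positive
class throughout this package)? `lipoclass` implements the full
chemometric workflow for that question — matrix assembly, normalisation,
region-of-interest (ROI) compression, Kennard–Stone splitting, feature
reduction by PCA or a genetic algorithm, classification by LDA, QDA, SVM
and KNN, and evaluation by sensitivity, specificity, ROC AUC and the
sensitivity–specificity F-score — together with a synthetic-cohort
generator, because no public cohort of this kind is available for testing.

## From peak lists to a matrix

**Common m/z axis.** Each sample owns its mass axis, so
`buildCommonAxis()` forms the union of all observed m/z values and merges
values closer than `mergeTolPpm` (default 5 ppm, comfortable for the
sub-2-ppm accuracy of a 140,000-resolution Orbitrap) by single-linkage on
the sorted union; a merged column sits at the intensity-weighted mean of
its members. Each sample's intensities are placed in their merged columns,
zero elsewhere. The result is deliberately much wider than any one peak
list — the in-silico analogue of 76 spectra becoming a 76 × 16540 matrix.

**Normalisation.** `normalizeRows()` scales every sample to unit sum of
squares. This removes overall-abundance differences (injection and
ionisation efficiency) while preserving relative peak pattern.

**ROI compression.** `roiSelect()` keeps exactly the columns in which at
least one sample is strictly greater than `thresholdFraction` (default
0.03) of the single global maximum of the normalised matrix. Three
readings were open and are fixed as follows: the reference maximum is the
*global* maximum, not per-sample maxima (a per-sample variant is available
via `perSample = TRUE`); a column is kept if *any* sample exceeds the
threshold, which retains peaks present in only one class; ties exactly at
the threshold are dropped ("strictly greater"). The pipeline order is
fixed — normalise first, then compress — and `roiSelect()` refuses an
unnormalised matrix unless forced, because the two orders do not commute.
One provenance subtlety: after compression the surviving columns no
longer sum to one per row (the dropped columns carried signal), so the
unit-norm validity check applies only between normalisation and
compression; both flags are kept for provenance.

The central container is `LipidFeatureSet`, a `SummarizedExperiment` with
features (merged m/z bins) in rows, samples in columns, and the two
provenance flags in its metadata.

## Splitting: Kennard–Stone 70/15/15

`splitKennardStone()` partitions samples deterministically with the
classical maximin algorithm: the first two selections are the
farthest-apart pair, and each subsequent selection maximises its minimum
Euclidean distance to everything already selected (ties always to the
lowest index, making the order fully reproducible). The most
design-spanning samples go to training, then validation, then prediction,
with validation and prediction sizes `floor(0.15 n)` each and training
absorbing the remainder. Run per class (the default), the 42 + 34 design
yields exactly 54/11/11 with a 6 NILM + 5 SIL prediction set — the only
split geometry consistent with prediction-set rates quantised in steps of
16.7% and 20%. A global (unstratified) variant is available; distances
are computed on the normalised, compressed matrix, i.e. on exactly the
features the classifiers see.

## Feature reduction

**PCA.** `pcaFit()` is a column-mean-centred SVD of the training rows
(no variance scaling — samples are already unit-norm), retaining ten
components by default, the score dimensionality the downstream
classifiers consume. Signs are fixed so each loading's largest-magnitude
entry is positive.

**Genetic algorithm.** `gaSelect()` evolves binary chromosomes (one bit
per m/z column) to minimise the average risk of misclassification on the
validation set,

$$G = \frac{1}{N_V}\sum_{n=1}^{N_V} g_n,\qquad
  g_n = \frac{r^2(x_n, m_{I(n)})}{\min_{I(m)\ne I(n)} r^2(x_n, m_{I(m)})},$$

where $r^2$ is the squared Mahalanobis distance to a class mean under the
pooled training covariance of the selected variables. The pooled form is
the default because a single shared covariance matches the LDA context the
risk comes from; a per-class option exists for the QDA pairing. The GA
settings follow the published protocol: 40 generations of 80 chromosomes,
crossover probability 0.60 (single-point), mutation probability 0.10,
three restarts from independent random populations (restart *r* seeded
`seed + r − 1`), best chromosome over all restarts returned. Choices the
protocol leaves open are fixed as tournament selection of size 2 and
elitism of one chromosome — elitism is what makes the per-generation
best-fitness history monotone. Initial populations switch each bit on
with probability 0.05 and chromosomes selecting more than `maxVariables`
(default 30) variables receive infinite fitness; both choices keep
covariance estimates well-posed on 54 training samples and reproduce the
one-to-few-dozen-variable regime this workflow is known for.

One reading deserves its own paragraph. "Mutation probability 0.10" is
implemented *per offspring* — each child has a 10% chance of one randomly
chosen bit flipping — not per bit. Per-bit flipping at 0.10 would
randomise about five of 50 (or ~28 of 278) bits in every child, which in
our experiments prevents the GA from ever refining a good subset (its
best fitness stalls above known optima), and under mutation–selection
balance would drive selected-subset sizes toward half the variable count,
irreconcilable with the small subsets this optimisation demonstrably
produces. The per-offspring reading is also the common convention in
variable-selection GAs.

A caution that the tests make explicit: with only 11 validation samples,
$G$ is a noisy functional, and subsets containing irrelevant variables
can genuinely score better than the truly informative ones on a given
split. The GA then optimises faithfully but the *statistic* overfits.
The planted-variable recovery checks therefore use 150 samples per class
(45 validation samples per class), at which size the risk landscape is
stable; this is a property of small-sample validation risk, not of the
optimiser.

## Classifiers

**LDA / QDA.** Scores follow the minimum-score rule:
$L_{ik} = (x_i-\bar x_k)^\top \Sigma_\text{pooled}^{-1}(x_i-\bar x_k) - 2\ln\pi_k$
and
$Q_{ik} = (x_i-\bar x_k)^\top \Sigma_k^{-1}(x_i-\bar x_k) + \ln|\Sigma_k| - 2\ln\pi_k$.
Priors default to training class proportions (equal priors available).
Any covariance whose condition number exceeds $10^{10}$ receives a ridge
$\lambda I$ with $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/p$ — GA subsets
can transiently exceed the training size, and QDA's per-class
covariances are estimated from as few as 24 samples.

**SVM.** `svmTrain()` solves the two-class soft-margin dual with a
deterministic sequential-minimal-optimisation variant using
maximal-violating-pair working-set selection (the $b_\text{up}/b_\text{low}$
optimality criterion), which converges reliably where the classic
single-threshold heuristic can cycle. Pairwise updates preserve
$\sum_i \alpha_i y_i = 0$ to machine precision; the bias is recomputed
after convergence from the margin support vectors. Five kernels are
provided: linear, quadratic and cubic $(\tau + x^\top z)^d$ with
$\tau = 1$ by default ($\tau \ge 0$ is the only stated constraint),
RBF $\exp(-\gamma\lVert x-z\rVert^2)$, and the MLP kernel
$\tanh(k_1 x^\top z + k_2)$ with the classic $k_1 = 1, k_2 = -1$. The MLP
kernel is indefinite: the solver takes clipped bound steps where the
curvature is non-positive and may return `converged = FALSE` at its
iteration cap — a documented contract, consistent with this kernel's
generally poor behaviour. The box constraint defaults to $C = 1$. The RBF
width defaults to the scale-aware $\gamma = 1/(p\,\mathrm{Var}(X))$: on
unit-norm spectra (and their PCA scores) pairwise squared distances are
of order $10^{-2}$, so the scale-free $1/p$ makes the Gram matrix
numerically constant and the fit degenerates to the majority class; the
variance-normalised form restores a well-conditioned kernel at any data
scale. An explicit `gamma` always wins.

**KNN.** Euclidean majority vote on the full compressed spectra, with
`k` chosen on the validation set by balanced accuracy over an odd grid
(default 1, 3, 5, 7, 9; ties to the smallest k). Only odd k is accepted
because no tie rule is defined for this two-class vote.

## Evaluation

With SIL positive: sensitivity $= \mathrm{TP}/(\mathrm{TP+FN}) \times 100$,
specificity $= \mathrm{TN}/(\mathrm{TN+FP}) \times 100$, and the F-score
is their harmonic mean evaluated on the percent scale and reported on
[0, 1] — note this is *not* the precision–recall F1. $F(0,0)$ is defined
as 0 by continuity, matching the convention of printing 0 for a model
with zero sensitivity. Zero denominators raise errors rather than
silently returning 0; the report builder converts them to NA cells. AUC
is the trapezoidal area under the empirical ROC curve, which equals the
Mann–Whitney pair-counting estimate with ties counted one half (a
property the tests assert to 1e-12). Because LDA, QDA and KNN emit hard
labels, their ROC scores are documented conventions: the discriminant
difference $L_{i,\mathrm{NILM}} - L_{i,\mathrm{SIL}}$ (larger = more
SIL-like), the raw SVM decision value before the sign, and the KNN SIL
vote fraction. Displayed tables round percentages to one decimal and
AUC/F-score to three; the F-score column is recomputed from the rounded
sensitivity and specificity so each printed row is internally
consistent.

## The synthetic cohort generator

`generateCohort()` emulates the statistical structure the analysis
assumes, not the chemistry. Per cohort it draws a shared background of
`nBackgroundPeaks` (default 300) peak positions, uniform over m/z
200–1200 (an optional `lowMzBias` weights density toward low m/z, where
real lipid profiles concentrate), with mean intensities log-uniform over
three decades so a few peaks dominate, as in real spectra. Per sample it
then: jitters every peak position with Gaussian noise of `mzJitterPpm`
(default 2 ppm, Orbitrap-like), so no two samples share a mass axis;
draws intensities log-normally around class-conditional means with CV
`intensityCv` (default 0.3), parameterised so the arithmetic mean equals
the class mean exactly — a marker's mean in its up-class is then
precisely `effectSize` times its mean in the other class; and adds
`nDecoyPeaks` (default 200) low-intensity decoys at per-sample random
positions under a `noiseFloor` (default 1% of the largest background
mean), which sit below the eventual ROI threshold and exercise the
compression step. The five default markers sit at the m/z values of the
lipids this workflow is known to discriminate on — 331.177 and 397.258
elevated in SIL, 369.227, 680.450 and 780.526 elevated in NILM — at
fold-change 5.

What the generator does *not* emulate: isotope patterns, adducts,
profile-mode peak shapes, ionisation suppression, correlated biological
covariates (age, medication, the LSIL/HSIL substructure of the positive
class), or the true intensity distribution of plasma lipid spectra — the
log-normal form is a stand-in chosen for its multiplicative-noise
realism, nothing more. Passing tests on this cohort demonstrate the
*pipeline machinery* recovers structure it was built to represent; they
say nothing quantitative about real plasma cohorts.

## Numerical choices and degenerate inputs

* Covariance ridge: $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/p$, applied
  only above condition number $10^{10}$.
* Kennard–Stone ties: lowest index, at both the starting pair and every
  subsequent step.
* ROI ties at the threshold: dropped.
* Empty GA chromosomes: repaired by switching one random bit on.
* All-zero samples: refused by name at normalisation.
* $g_n$ with a zero numerator is 0 even if the denominator is also zero;
  an infinite ratio propagates honestly to an infinite $G$.
* SMO tolerance $10^{-4}$ on the KKT gap; iteration cap
  `maxPasses * n` pair updates.
* The generator restores the caller's RNG state; every stochastic stage
  of the pipeline derives its stream from the single root seed (the
  generator uses it directly, the GA uses `seed + 1000`), and a
  fixed-seed run is byte-identical.

## Annotation

`differenceSpectrum()` (mean NILM spectrum minus mean SIL spectrum — a
negative entry means more intense in SIL) feeds
`rankDiscriminantFeatures()`, and `matchReference()` annotates the
top-ranked m/z values against a packaged five-lipid reference table with
signed ppm errors. Formulas in the table are treated as the intact
detected-ion compositions, with no adduct arithmetic by default: the
convention behind vendor-reported mass errors for these assignments is
not reconstructible (no single neutral, protonated or electron-corrected
convention reproduces them), so the package computes errors under its own
documented convention and provides optional [M+H]+ / [M+Na]+ modes with
electron-mass correction for users who know theirs. The default match
tolerance is 10 ppm — wide enough to absorb that convention uncertainty
while the five reference lipids remain far apart in mass. One reference
value is internally inconsistent in its source (680.450 vs 680.455 in
different places); the packaged table uses 680.450.

## Known limitations

* **Majority-class bias under the null.** With 42 vs 34 samples the
  training set is imbalanced (30 vs 24), and under no class effect an
  unweighted soft-margin SVM — like proportional-prior discriminants —
  drifts toward the majority class: prediction-set sensitivity falls
  well below 50% while specificity rises above it, even though balanced
  accuracy stays at chance. An independent SVM implementation reproduces
  the identical predictions, so this is a property of the method, not of
  this implementation. The package deliberately does not re-weight
  classes or priors to hide it; the test suite states the idealised
  symmetric expectation and documents that the unweighted method fails
  it.
* Validation-risk overfitting at small validation sizes (see the GA
  section).
* Two-class only; multiclass coupling is out of contract.
* Peak lists only: no mzML/profile-mode parsing, no baseline correction,
  no chromatographic dimension.

## Problem sizes used by the tests

The test suite exercises cohorts of the study geometry (76 samples, ~60
background peaks for the fast pipeline checks, the full 300 + 200-decoy
default for the generator checks), brute-force oracles at n ≤ 12 samples
(Kennard–Stone) and ≤ 50 variables, ten-seed averages for the stochastic
recovery checks and twenty seeds for the null check. These sizes were
chosen so each check is stable at its stated tolerance while the whole
suite stays quick to run.
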