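---
title: "From regional ALFF to single-digit discriminative connections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From regional ALFF to single-digit discriminative connections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alffconn)
```

## The problem

Type 2 diabetes raises the risk of cognitive impairment, and resting-state
fMRI offers two complementary windows on the underlying brain changes:
regional spontaneous activity, indexed by the amplitude of low-frequency
fluctuations (ALFF), and inter-regional functional connectivity, indexed by
the Pearson correlation of regional BOLD time courses. `alffconn`
implements a pipeline that uses the first to constrain the second: atlas
subregions with group-altered ALFF anchor a candidate pool of connections,
which a two-stage sparse selection then reduces to a handful of
discriminative edges that feed a kernel classifier. Because the clinical
cohorts such a pipeline targets are small (tens of subjects per group), the
entire selection is wrapped in leave-one-out cross-validation so that no
stage ever sees the held-out subject's category.

All stages are verifiable without MRI data through a synthetic generator
that plants known ALFF deficits and known connectivity shifts.

## The measurement model

**ALFF.** For a time series of length $T$ sampled every `tr` seconds, the
series is linearly detrended, Fourier transformed, and the square root of
the one-sided power spectrum is averaged over the discrete frequencies in
the 0.01–0.08 Hz band (endpoints inclusive on the frequency grid
$k/(T \cdot tr)$). We use the periodogram without windowing or segment
averaging — the plain transform-power-sqrt-mean chain — and the one-sided
scaling $2|X_k|^2/T$. The absolute scale is arbitrary: each subject's map
is standardized by its whole-brain (whole-mask) mean, which removes any
consistent spectral scaling and equates subjects' global levels. A
standardized map has mask mean exactly 1; ALFF itself is linear in signal
amplitude. A band that contains no resolvable frequency is an error
(reported with the grid step), not a silent zero.

**Connectivity.** Each subject's functional network is the $R \times R$
matrix of Pearson correlations between regional mean time courses, raw $r$
without Fisher transformation. Constant time courses are an error naming
the offending region.

## Locating impaired subregions

At voxel resolution the pipeline follows the standard mass-univariate
chain: a one-way ANOVA across the three groups (threshold $p < 0.05$
uncorrected, configurable — the threshold of the masking step is a free
parameter here) defines an analysis mask; within it, two-sample t maps are
assessed by permutation testing of the maximum threshold-free cluster
enhancement (TFCE) statistic, which controls the family-wise error rate
without a fixed cluster-forming threshold. TFCE integrates
$e(h)^E h^H\,dh$ over supra-threshold heights with the literature's default
$E = 0.5$, $H = 2$, and step $dh = \max|t|/100$; the negative tail is
enhanced on $-t$ and carries its sign. Components of the corrected
significance mask smaller than 20 voxels are excluded; surviving clusters
are overlapped with the atlas label volume, subregions are ranked by
overlap volume (ties to the smaller region id for determinism), and the
anchor set takes the top 15 subregions with *decreased* ALFF, completed by
subregions with increased ALFF when fewer than 15 decreased ones exist —
so every comparison works with the same anchor count. "Decreased" always
refers to the patient-minus-control contrast.

Permutations enumerate all label exchanges exactly when fewer than the
requested number exist; the permutation null is computed within the ANOVA
mask (a flag restricts or widens this). Connectivity for cluster labelling
is 6-neighbour (faces), configurable to 18/26.

For datasets that carry regional time series only, the package applies the
same logic at region resolution: per-region two-sample t tests on
standardized regional ALFF, ranking by effect magnitude in place of
overlap volume, decreased first. This keeps every leave-one-out fold cheap
enough to re-run the whole selection, which is the property the
cross-validation design actually needs; the voxel path is exercised
end-to-end in its own right at small grid sizes.

## From anchors to features

All connections touching at least one anchor are candidates: for $a$
anchors among $R$ regions, $a(R-a) + a(a-1)/2$ columns — 3570 for
$a = 15$, $R = 246$ — in deterministic lexicographic pair order. The
attribute block pairs the binary diagnosis label with age and sex
(1 = male, 0 = female) so that the selection can explicitly separate
diagnostic from nuisance association.

## Two-stage sparse selection

**Sparse CCA.** The first stage maximizes $v_1^\top X_1^\top X_2 v_2$
subject to $\|v_i\|_2 \le 1$ and $\|v_i\|_1 \le \lambda_i$, solved by
penalized matrix decomposition: alternating soft-threshold projections of
each side onto the $\ell_1$-ball intersected with the unit sphere, the
threshold found by bisection, successive components by rank-one deflation.
Both blocks are centered and variance-scaled before fitting — the
constraints are scale-sensitive, and an unscaled age column (sd ≈ 7 years
against 0/1 diagnosis) would otherwise dominate every component in a way
deflation cannot repair. Because the alternating updates are only locally
convergent, each component restarts deterministically from the leading
singular vector and from each row of the cross-product, keeping the best
objective; the fit is therefore seed-free. Within the nested pipeline
$\lambda_1 = 1$, which makes every attribute projection exactly one-hot,
so the component "associated only with diagnosis" is well defined and the
age/sex components are cleanly separated (the standalone function defaults
to $\lambda_1 = 1.2$). $\lambda_2$ is chosen by bisection so the leading
component keeps roughly 50 connections — small enough for the next stage
to prune, large enough not to truncate true signal; both bounds are
configurable.

**ARD sparse logistic regression.** The diagnosis component's connections
enter a logistic regression whose weights carry zero-mean Gaussian priors
with per-weight inverse variances (relevance parameters). The fit
alternates Newton maximization of the penalized likelihood (bias
unpenalized) with evidence updates
$\alpha_d \leftarrow (\gamma_d + 2a_0)/\theta_d^2$,
$\gamma_d = 1 - \alpha_d \Sigma_{dd}$, pruning a weight once its relevance
exceeds $10^8$; convergence is declared when no weight moves by more than
$10^{-6}$, with a 500-iteration cap. The hyperprior shape $a_0 = 1$ makes
the relevance of merely chance-correlated features diverge decisively:
with the plain update ($a_0 = 0$) any feature whose chance marginal
$t^2 > 1$ retains a small weight indefinitely, which at 50 candidate
noise features means a dozen spurious survivors in every null fit. With
$a_0 = 1$ the selected set is empty on label-independent data and exactly
the planted support in recovery simulations, at no cost to sensitivity at
the signal strengths of interest (single-feature $t > 5$). When the
sparsity-promoting update empties the set entirely, the fold refits with
the plain update before being declared failed — so null data yields
chance-level predictions rather than no predictions. A relevance floor of
$10^{-3}$ keeps weights bounded by the prior under complete separation.

## Classification and validation

An RBF-kernel SVM is trained on the surviving connections, with cost and
kernel width chosen by grid search (powers of two, $C \in 2^{-5..15}$,
$\gamma \in 2^{-15..3}$) over stratified 5-fold cross-validation inside
the training set; ties resolve to the smallest cost then the smallest
width, and the inner-split seed is fixed and recorded. The outer loop is
leave-one-out over the two-group comparison: anchor selection, feature
standardization (training mean/SD only), sparse CCA, ARD logistic
regression and the grid search are all recomputed per fold from the
training subjects alone. The probe we use in testing — perturb only the
held-out subject's signals and check the fold's selected set, anchors and
hyperparameters do not move — holds on every fold by construction, since
the held-out row enters nothing but the final prediction.

Connections are ranked across folds by *repeat times* (the number of folds
selecting them; ties by mean absolute weight, then pair id), and the
accuracy-versus-count sweep evaluates the top-$k$ ranked connections for
$k = 1..k_{max}$, choosing the smallest $k$ attaining the best accuracy. A
principal-component baseline sweep is provided for comparison. A separate
fixed-feature protocol evaluates a predetermined connection set with only
the SVM retrained per fold.

Performance is reported as the confusion matrix, accuracy, precision,
recall, specificity, F1 (percentages to one decimal), and AUC computed as
the normalized rank statistic over decision scores pooled across held-out
folds (the pooling convention is a documented choice; for hard LOOCV
predictions the per-fold and pooled accuracies coincide). Undefined rates
(zero denominators) are reported as NA, never as 0.

## The synthetic generator

Signals are filtered Gaussian processes: a unit-variance band-limited
(0.01–0.08 Hz) component plus broadband white noise (`noise_sd`, default
0.3). This makes every planted effect analytically controllable:

* An ALFF deficit with factor $f$ multiplies the band-limited amplitude of
  the designated regions in the designated groups, so the regional ALFF
  ratio between groups approaches $f$ (up to the small in-band noise
  floor). The factor is an amplitude — halving ALFF means factor 0.5 and
  band power $f^2 = 0.25$.
* A planted connection mixes a shared band-limited latent into both
  members of a pair with weight $w$ solved from the target correlation,
  compensating the dilution by broadband noise and by any ALFF scaling of
  the endpoints; targets whose required $w$ exceeds 0.99 are rejected as
  unreachable rather than silently missed. A region may join at most one
  planted pair per group.
* Cognitive scores can be regenerated to correlate at a chosen level with
  a chosen connection's strength, preserving the scale's mean and SD.

Default group sizes are 19/31/39 (patients with impairment / patients with
normal cognition / controls), the retained sizes of the reference cohort;
demographics (age means near 60, male fractions near 0.55, MoCA above or
below the 26-point impairment threshold) mirror the cohort's participant
table. One master seed draws per-subject substreams, so a subject's
signals do not depend on group ordering and runs are bit-reproducible.

What the generator does *not* emulate: hemodynamic response shapes, head
motion, physiological noise, scanner drift, spatial autocorrelation beyond
region blocks, and the correlation structure of real resting-state
networks. Passing recovery tests therefore demonstrates the pipeline's
correctness and calibration under its own assumptions, not clinical
performance; the reference study's real-data AUCs (0.91/0.90/0.86) are not
reproducible from synthetic data and are not targets of the test suite.

## Numerical choices and degenerate inputs

* Band endpoints are inclusive on the discrete grid; an unresolvable band
  errors with the grid step. Constant series inside a mask map to ALFF 0
  with a warning.
* TFCE requires finite maps; `dh` defaults to 1% of the map maximum.
* Cluster ranking ties break to the smaller region id; pair ordering is
  lexicographic; the sweep breaks accuracy ties to the smaller k.
* SCCA declares a zero cross-product degenerate (objective 0) instead of
  iterating; non-convergence warns with the objective trace attached.
* Fold failures (no anchors, empty selection) are excluded from metrics
  with a warning and counted in the report — explicit rather than silent.
* The problem sizes used in the test-suite recovery runs (e.g. 15 + 15
  subjects at 246 regions and 230 timepoints for the end-to-end check;
  200 repetitions at 99 permutations on a 6×6×6 grid for the family-wise
  error calibration) are chosen so the full suite documents the method at
  realistic dimensionality while remaining quick to re-run.

## Known limitations

The region-level anchor path substitutes per-region tests for the voxel
TFCE chain inside the outer loop; at voxel resolution the nested design is
exercised at small grids only. The ANOVA mask threshold is a free
parameter the reference methodology leaves unstated, as are the exact
sparse-CCA bounds and the SLR solver variant; all are configurable, and
the defaults are recorded above. Correlations between connection strength
and cognitive scales pool the subjects of a comparison; a patients-only
convention would be equally defensible and is a one-line change for the
caller.
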