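---
title: "Methods: case-control analysis of untargeted plasma lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control analysis of untargeted plasma lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidcc` implements a complete case-control analysis chain for untargeted
LC-MS lipidomics feature tables of the kind produced by peak-alignment
software: a samples-by-features matrix of positive peak areas with missing
entries, accompanied by per-sample clinical metadata (diagnosis, age, sex,
APOE-&epsilon;4 allele count, acquisition batch, MMSE, statin use, smoking).
The motivating design is an elderly memory-clinic cohort with three
diagnostic groups — healthy controls (CTL), mild cognitive impairment (MCI)
and Alzheimer's disease (AD) — plus pooled-plasma quality-control (QC)
injections interleaved across batches. This vignette records the models,
the defaults and the numerical choices, and what the synthetic-data tests
do and do not establish.

## Pre-treatment chain

The pre-treatment operations are strictly ordered, and each matrix carries
a scale tag (`raw -> normalized -> log2 -> corrected -> imputed`) so that an
out-of-order call is an error rather than a silent mistake.

1. **Total-mean-area normalisation.** Each sample's present intensities are
   scaled by (mean of per-sample totals) / (that sample's total), the
   convention of common alignment software. A sample with no present values
   is an error naming the sample.
2. **Detection filtering.** A feature is kept only if detected (present and
   positive) in at least 80% (default) of the samples of *every* diagnostic
   group and of *every* batch; pooled-QC injections are excluded from the
   rates. The kept set is monotone in the threshold.
3. **log2 transform.** Raw peak areas are strongly right-skewed; log2 makes
   most features approximately normal and makes effects multiplicative.
4. **Batch correction.** See below.
5. **PCA QC.** PCA on mean-centred, unit-variance features (a provisionally
   mean-imputed copy is used, since imputation proper happens after outlier
   removal). A sample is flagged when its score on one of the two leading
   components exceeds 3 score-standard-deviations — a default; no universal
   rule exists. QC tightness is summarised as the mean distance of QC
   samples to their centroid over the mean distance of all samples to the
   grand centroid.
6. **KNN imputation.** Within each diagnostic phenotype separately (QC
   samples form their own group), a missing value of feature *f* in sample
   *s* is the unweighted mean, over the *k* = 10 features nearest to *f*,
   of their values in *s*. Feature-feature distance is the root mean square
   difference over the group's samples where both features are present;
   candidates must overlap *f* on at least half of the group and be present
   in *s*. The neighbour space is features, not samples, matching the
   established KNN-imputation semantics for expression-style matrices.
   A feature with no value at all within a group falls back to its grand
   mean across all samples, with a warning — the detection filter makes
   this rare, but degenerate inputs must not crash.

### Empirical-Bayes batch correction

Batch effects are modelled per feature *f* and batch *b* as

$$ y_{fs} = \alpha_f + X_s\beta_f + \gamma_{fb} + \delta_{fb}\,\varepsilon_{fs}, $$

an additive location shift and a multiplicative scale factor around the
feature's grand mean (plus optional protected covariates $X$). Features are
standardised by their fitted grand mean and pooled variance; per-batch
location and scale estimates $\hat\gamma_{fb}, \hat\delta^2_{fb}$ are then
shrunk towards batch-level priors — normal for location, inverse-gamma for
scale — whose hyperparameters are moment-matched across features, by the
standard iterative conditional solution (convergence tolerance $10^{-8}$,
cap 1000 iterations). Missing entries are ignored during estimation and
preserved in the output. A single batch is a no-op; a singleton batch is an
error. The parametric priors only are implemented; the non-parametric
variant is out of scope. By default no covariates are protected: the
generator's batches are balanced across diagnosis, which bounds the signal
loss, and the choice is configurable.

Two numerical facts discovered while validating against planted effects
deserve a note, because they constrain what any correct implementation can
promise. First, when every feature carries the *same* planted
$\gamma = \pm 1$, the across-feature prior variance $\bar\tau^2$ is pure
sampling noise, so shrinkage retains roughly half of the per-feature
estimation noise: at 200 samples per batch the per-feature post-correction
batch gap has mean $\approx 0.05$ even though the batch *means* agree to
$\approx 10^{-3}$. The tests therefore assert the batch-mean gap and bound
the per-feature residue at the noise level (the installed reference EB
implementation behaves identically, and the two agree to $10^{-4}$ on
complete data). Second, the EB adjustment converges to plain per-batch
standardisation as $n$ grows, but the prior term decays as $O(1/n)$ while
multiplying extreme z-scores, so at $n = 5000$ the *mean* absolute
deviation is well under $10^{-2}$ while the maximum over all entries can
still reach a few times that. Convergence is asserted in mean absolute
deviation, under heterogeneous planted $\delta^2$ (log-normal, sd 0.5 on
the log scale): with near-constant $\delta^2$ the moment-matched
inverse-gamma prior becomes degenerately strong and the large-$n$ argument
does not apply.

## Single-analyte association

Each feature (log2 scale, mean-centred) enters a maximum-likelihood
logistic regression of AD-vs-CTL status adjusted for APOE-&epsilon;4 allele
count, age, sex and batch indicators (first batch as reference). Odds
ratios are per log2 unit with Wald 95% intervals and p-values — the
standard glm-style reporting; profile-likelihood intervals are not used.
Non-convergence and (quasi-)separation are flagged rather than hidden, and
the estimates are still returned. Multiplicity is controlled by
Benjamini-Hochberg step-up q-values (via `p.adjust`; the test suite checks
it against a brute-force step-up oracle). Secondary models add a
feature-by-APOE product term and report its Wald p-value; interaction
results are reported but never used for feature selection. Cohort
description uses one-way ANOVA with Tukey HSD follow-up for continuous
variables, Pearson chi-square (no continuity correction) for categorical
ones, and Spearman correlation (the default; Pearson optional) for the
relation of feature levels to MMSE — rank-based because MMSE is a bounded
ordinal score.

## Two-stage classifier

The AD and CTL samples are split 2/3 training / 1/3 held-out test,
stratified by class by default; a `balanced` mode (equal class counts in
training, the training fraction of the smaller class) is also provided
because both designs are defensible and the rounding conventions are
explicit: stratified rounds per class, balanced floors. The test partition
ids never enter any later selection step.

**Stage 1 — importance rank aggregation.** The training set is resampled
100 times (default) into stratified 75/25 parts, drawn without replacement
by default (a with-replacement mode exists). Per resample a random forest
(ntree = 500) is fitted for each `mtry` in
$\{\lfloor\sqrt p\rfloor/2, \lfloor\sqrt p\rfloor, 2\lfloor\sqrt p\rfloor\}$
and scored by AUC on the 25% part; the best-`mtry` forest's importance
ranking (impurity decrease by default, permutation importance by flag;
rank 1 = most important, ties broken by feature order for determinism)
contributes to each feature's summed rank. The overall `mtry` is the grid
value with the best mean resample AUC. The top 10% of features by summed
rank are selected, with the count rounded half-to-even (so 10% of 573
features is 57, not the ceiling 58) and ties broken by mean raw importance,
then feature order. The APOE-&epsilon;4 count can be appended as a
candidate predictor by flag; it is excluded by default.

**Stage 2 — recursive feature elimination.** On the selected candidates, a
second round of stratified 75/25 resamples fits a forest on all candidates,
takes that resample's importance ranking once (re-ranking at every size is
not performed — the ranking-once convention), and refits on the top-*s*
features for each subset size *s* in 50, 45, …, 10, 9, …, 2 (intersected
with the candidate count), recording the 25%-part AUC. The selected size is
the smallest whose mean AUC is within 1.5% of the profile's best — small
without sacrificing performance. The final forest is fitted on the complete
training data restricted to the selected subset and evaluated once on the
untouched test set (majority-vote calls at vote fraction 0.5; AUC from vote
fractions, computed by the Mann-Whitney rank formula and property-tested
against a concordant-pair count). The final model can then be applied to
samples that took part in neither training nor testing — in the motivating
design, the MCI group, whose calls indicate whether intermediate cases look
more like cases or controls.

A property worth knowing: on *null* data the inner rfe profile sits
systematically **below** 0.5, not at it. Selecting features by their 75%-part
association forces their 25%-part association towards the opposite sign
within a fixed cohort, so internal resampling is pessimistic, never
optimistic, under the null; the outer held-out AUC is unbiased (mean
$\approx 0.5$ under permuted labels). Tests assert exactly this.

## Synthetic cohorts

No public dataset accompanies the motivating design, so the generator is a
first-class, tested module with known ground truth. Defaults describe the
study conditions: 40 CTL / 48 MCI / 36 AD plus 20 pooled-QC injections in 4
batches; 1878 features; log2 intensities
$\mathcal N(\mu_f, \sigma_f)$ with $\mu_f \sim U(10, 20)$,
$\sigma_f \sim U(0.3, 1.0)$ (reproducing the skewed raw distributions);
informative features shifted down by half the effect in MCI and the full
effect (default 1.5 log2 units) in AD, giving the control > MCI > AD trend;
batch effects drawn from the same location/scale model the correction
assumes ($\gamma \sim \mathcal N(0, 0.5^2)$, $\delta^2$ scaled
inverse-gamma with mean 1, shape 20) so that parameter recovery is
testable; QC rows equal to the pooled mean profile plus batch effects and
0.05-sd noise. Covariates follow the demographic model of elderly
memory-clinic cohorts (group-wise age ~78 ± 6-8; MMSE 29.0/26.9/21.5
truncated to [0, 30]; APOE-&epsilon;4 genotype frequencies rising from CTL
to AD; roughly balanced sex). One AD sample is planted as a gross outlier
by default, so the QC stage has real work (and its removal leaves 35 AD of
36 — the generator models the recruited-minus-excluded bookkeeping of real
cohorts).

Missingness is left-censored plus random: entries below a feature's 5th
percentile (default) go missing with probability 0.9, and a further 1% is
removed completely at random — typical post-alignment missingness for
LC-MS peak tables. Censoring interacts with the detection filter exactly
as in real data: the most strongly AD-depleted markers are the most likely
to fall below detection in the AD group, so an occasional informative
feature is lost before modelling. That is a property of the measurement
process, not a bug, and the end-to-end recovery expectations account for
it.

What the generator does *not* emulate: chromatographic drift,
retention-time misalignment, adducts and isotopes, correlated feature
blocks (co-eluting lipid families), or non-Gaussian heavy tails. Passing
tests on synthetic cohorts therefore demonstrate algorithmic correctness
and statistical calibration, not field performance on real spectra.

## Problem sizes used in tests

The shipped test-suite and acceptance script exercise the chain at reduced
scale, chosen to give stable Monte-Carlo verdicts while keeping a full run
in minutes: end-to-end runs use 150-feature cohorts with 6 informative
features, 30 bootstrap resamples per stage and 10 seeds (plus matched
permuted-label nulls); oracle suites use 1000 random BH vectors, 500
random AUC score sets and all 2x2 tables with margins at most 10;
calibration suites use 1000 replicates. Defaults in the package remain the
full study conditions (1878 features, 100 bootstraps).

## Known limitations

* ComBat here is parametric-prior only, and its `BatchModelParams` report
  the standardized-scale estimates (multiply by $\sqrt{\hat\sigma^2_f}$
  for data-scale offsets).
* Wald inference degrades under separation; flagged rows should be treated
  as directional evidence only.
* The size-tolerance rule deliberately returns *minimal* models; when a
  couple of features saturate the AUC profile, the final subset will not
  contain every informative feature, and marker *recovery* should be read
  off the stage-1 top-10% selection.
* The KNN-imputation distance uses pairwise-complete overlap and so can be
  noisy for features near the detection threshold in small groups.
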