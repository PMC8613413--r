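---
title: "Individualized rTMS targeting, dosing, and experiment simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized rTMS targeting, dosing, and experiment simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimpipe)
```

## What the package computes

`stimpipe` re-implements, as tested and reusable R code, an individualized
pipeline for online repetitive transcranial magnetic stimulation (rTMS)
experiments on working memory:

1. **Target selection.** Candidate frontal (left mid-frontal gyrus) and
   parietal (left lateral-parietal) atlas regions are screened by a
   two-condition rule: a region must have at least 25% of its voxels
   significantly activated (z > 1.96) in the task contrast between an
   alphabetization task (DRAT) and a maintenance task (DRMT), and among the
   regions passing that gate the one with the highest *modal
   controllability* on the subject's structural connectome is chosen.
2. **Coil placement and dosing.** The target's center is projected to the
   nearest scalp vertex, offset outward by the measured hair thickness, and
   the coil is twisted so the second phase of the induced E-field aligns
   with the inward normal of the nearest sulcal wall. The stimulator
   amplitude is calibrated so the region's E100 exposure — the 100th
   largest E-field magnitude over its voxels — equals a reference of
   56 V/m, with %rMT safety bookkeeping.
3. **Task calibration.** A 2-down-1-up staircase practice session is fitted
   with a logistic psychometric function (guess rate 0.5), and Easy /
   Medium / Hard set sizes are derived from an 82% accuracy threshold.
4. **Experiment and analysis.** A counterbalanced two-visit factorial
   schedule (720 trials; 16 condition cells for Cohort 1, 32 for Cohort 2)
   is generated, simulated against Bernoulli observers, and analyzed with
   within-subject ANOVAs, Bonferroni post-hocs, paired Cohen's d, a
   percent-change rTMS effect, and covariate correlations.

A seeded synthetic-cohort generator supplies every input the stages
consume, so the full pipeline runs end to end without neuroimaging data.

## Modal controllability

For a symmetric streamline-count matrix $W$ with zero diagonal, the
dynamics matrix is normalized as $A = W / (1 + \lambda_{\max}(W))$, which
places all eigenvalues strictly inside the unit circle. With orthonormal
eigenvectors $V$ and eigenvalues $\lambda_j$ of $A$, each node is scored

$$\phi_i = \sum_j \left(1 - \lambda_j^2\right) v_{ij}^2 .$$

Nodes strongly coupled to fast-decaying modes (small $|\lambda_j|$) score
high: they can push the network into hard-to-reach states. This is the
standard discrete-time definition; a $(1-\lambda_j)^2$ weighting variant is
available behind a switch but off by default, and raw streamline counts are
used without log-transform or binarization. Because the input is symmetric
by contract, a symmetric eigendecomposition suffices and $\phi$ is
invariant to eigenvector sign conventions. The test suite checks the
implementation against an independent SVD-based brute-force oracle to
1e-10, together with the closed forms ($\phi \equiv 1$ for the empty graph;
$\phi = 0.75$ for both nodes of the single-edge graph).

## Activation mapping

Task blocks are convolved with the canonical double-gamma hemodynamic
response function — gamma densities with shape 6 (response) and shape 16
(undershoot), unit rate, peak/undershoot ratio 6, 32 s support. The
parameterization is exposed in `build_design_matrix()` since only the
family, not the constants, is dictated by convention. The GLM is ordinary
least squares per voxel; the DRAT−DRMT contrast t statistic is mapped
through the t CDF to a standard normal quantile (computed on the log scale
so extreme voxels keep their magnitude), and voxels with zero residual
variance receive a flagged signed-infinity sentinel. Binarization uses the
*strict* inequality z > 1.96, so a voxel exactly at threshold does not
count. No voxel-level multiplicity correction is applied, matching the
procedure being reproduced. Preprocessing (motion correction, smoothing,
high-pass filtering, spatial normalization) is out of scope: the stage
consumes synthetic BOLD or ready z-maps.

## Target rule and ROI centers

The gate comparison is `fraction >= 0.25` ("at least 25%"). Ties in
controllability break by ascending label so decisions are deterministic,
and an empty passing set raises an explicit "no eligible target" error
rather than falling back silently. Region centers are mass centroids of
the label's voxels; when the centroid falls outside the mask (a C-shaped
region), it snaps to the nearest in-mask voxel center before the
MNI-to-native affine is applied — a stimulation target must lie in tissue.
Qualitative exclusions (e.g. candidate regions whose stimulation would be
painful) are honored only through an explicit exclusion-list argument,
never inferred.

## Dosing

The physical assumption that makes calibration a single rescaling is that
the induced field is exactly linear in coil drive:
$E(x; d) = (d/d_{\mathrm{ref}})\, E(x; d_{\mathrm{ref}})$. The synthetic
coil model is $|E|(x) = A\, d\, e^{-\lVert x - c\rVert / \lambda}$ with
$A = 6$ V/m per %MSO and $\lambda = 20$ mm — any drive-linear, strictly
distance-decreasing form would do; this one keeps every geometric check
analytic. E100 is the 100th largest magnitude over the region's voxels;
for regions under 100 voxels the *smallest* magnitude is used with a
warning flag, a conservative fallback that never overestimates dose.
Calibrated amplitudes above 100 %MSO are capped with a device-limit flag.
The %rMT conversion is `100 * amplitude / rMT`, rounded for reporting with
full precision retained, and flagged above a configurable 130 %rMT
guideline. On the default synthetic anatomy the frontal candidate cap
sits at a larger cortical radius (shallower under the scalp) than the
parietal cap, so calibrated frontal amplitudes are systematically lower —
the same depth asymmetry the published amplitude table shows.

The packaged 29-row amplitude table ships as a plain TSV; `audit_amplitude_table()`
recomputes its column means (53.55, 39.83, 78.31, 47.72, 92.83) and checks
every row's %rMT against `round(100 * %MSO / rMT)` within ±1. The printed
parietal %MSO standard deviation of 10.43 computes as 10.4365 with the
sample (n−1) denominator, so it appears truncated rather than rounded;
the audit asserts agreement at printed precision with that slack.

## Psychometrics

The staircase raises the set size after two consecutive correct responses
and lowers it after any error, clipped to bounds (2, 12) with start 4 —
the step size and bounds are not dictated by the procedure being
reproduced and were chosen once so Hard set sizes land in the observed
5–8 range. The theoretical convergence point of a 2-down-1-up rule is the
70.7%-correct level ($p^2 = 0.5$); the acceptance suite verifies the
median late-practice accuracy of 200 simulated observers lies in
[0.65, 0.76].

The psychometric model is a logistic in set size with the guess rate fixed
at 0.5 (binary Valid/Invalid response) and the lapse fixed at 0.02:

$$\mathrm{acc}(s) = \gamma + \frac{1 - \gamma - \mathrm{lapse}}{1 + e^{k (s - s_0)}} .$$

Fitting is binomial maximum likelihood with multi-start Nelder–Mead over
$(s_0, \log k)$; all practice DRAT trials are pooled regardless of block.
All-correct or all-error data raise a "poor behavioral performance" error,
mirroring the exclusion path of the original procedure.

One rule needed interpretation: "Easy is the smallest set size with
accuracy above threshold" is degenerate on a decreasing accuracy curve
(the smallest set size passes trivially). Because Medium and Hard are
defined as the next two set sizes *lower along the fitted curve*, the
implemented reading is the **largest** set size still meeting the 82%
threshold; Medium and Hard are `easy + 1` and `easy + 2`. This is flagged
in the function documentation as well, not silently adopted.

## Experiment engine

Four randomization groups form the 2×2 of target order across visits and
stimulation order within the first visit; the second visit reverses the
stimulation order, so each group's four visit-halves cover
{active, sham} × {DLPFC, LPC} exactly once. The exact contents of the
original randomization table are not published; this counterbalancing is
the natural one consistent with its description. Each visit has 12
blocks × 30 trials with tasks alternating block-by-block, the half break
between blocks 6 and 7, rTMS trains on every other trial starting with
the first, and probe validity balanced 15/15 per block. Cohort 2
intermixes Easy and Hard balanced 15/15 within block (rather than fully
at random) to keep per-cell counts near their expected ~22. Letter arrays
are drawn without replacement from a 20-consonant pool (vowels excluded to
avoid chunkable words); valid probes carry the letter's alphabetical rank
(DRAT) or original position (DRMT), and "new" probes (letters outside the
array) are excluded from the design. Simulated observers apply injected
stimulation effects only on trials that actually received a train under
active stimulation.

## Observer model and what the synthetic cohort does (and does not) show

Observers are Bernoulli responders on the logistic curve above, plus a
truncated-normal reaction time (floor 200 ms) and an additive
per-(target, task, stimulation) accuracy shift used to inject ground-truth
rTMS effects. Defaults: $s_0 = 6.5$, $k = 1.2$, lapse 0.02 (population
spread $s_0 \sim \mathcal{N}(6.5, 0.5)$, clipped to [5, 8]) — chosen once
so the derived Hard level lands near the observed ~68% DRAT accuracy; they
are not estimates of any individual. The observer carries one extra knob
the minimal model lacks: a +0.18 accuracy bonus on the maintenance task,
without which the synthetic cohort could not display the robust Task main
effect (DRMT ≈ 88% vs DRAT ≈ 69% at Hard) around which the analyses are
organized.

The generator emulates the *statistical structures the pipeline assumes* —
symmetric nonnegative connectomes, design-locked BOLD with Gaussian noise,
drive-linear fields on concentric-sphere anatomy, logistic observers. It
does not emulate cortical folding, realistic field physics, spatially
correlated fMRI noise, learning or fatigue across blocks, or
response-time/accuracy coupling. Passing tests therefore certify the
*procedures* (rules, algebra, calibration, inference), not performance on
real neuroimaging data.

## Statistics

The repeated-measures ANOVA is the standard balanced fully-crossed
within-subject decomposition: every effect is tested against its own
interaction with subjects. It is implemented directly (inclusion-exclusion
over marginal means) rather than through a model-fitting wrapper because
the package needs the sums-of-squares conservation invariant
($SS_\text{total} = SS_\text{subject} + \sum SS_\text{effect} + \sum
SS_\text{error}$, checked to 1e-8), both eta-squared flavors, and a fast
path for calibration studies; `stats::aov` with an `Error()` stratum
serves as the independent oracle in the test suite, and a two-level
factor's F reproduces the squared paired t to 1e-8. Classical
($SS_e/SS_\text{total}$) and partial ($SS_e/(SS_e+SS_\text{err})$)
eta-squared are always reported side by side because published values mix
the two flavors. Subjects with any empty design cell are dropped listwise
with a warning.

The rTMS effect is the percent change of the across-task average accuracy
restricted to Hard trials, with sham as the denominator: tasks are
averaged *before* the ratio. Cohen's d for paired active/sham differences
uses the sample SD of the differences. Pearson correlations with dosing
and targeting covariates are computed separately per stimulation target.
Post-hoc contrasts are paired t tests with Bonferroni adjustment
(`min(1, m p)`), the family size an explicit argument because published
family sizes are not always stated.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-residual voxels are
flagged sentinels, not silent numbers; empty gate-passing sets, empty
regions, all-correct psychometric data, zero sham accuracy, constant
covariates, and zero-variance paired differences all raise typed errors.
Determinism is part of the contract: every generator is a pure function of
its seed, selection and ordering rules break ties lexicographically, and
`run_pipeline()` reports a content hash over its results so reruns can be
compared bit for bit.

The calibration studies run at sizes chosen to give each estimate
comfortable Monte-Carlo resolution on a single CPU: 200 observers for the
staircase equilibrium (binomial SE ≈ 0.01 on the median's neighborhood),
500 practice runs for the midpoint-recovery bias (SE ≈ 0.013 set-size
units against a 0.2 bound), 5000 null replications for the ANOVA type-I
rate (SE ≈ 0.003 against a ±0.01 band), 50 replicate 29-subject cohorts
for effect recovery (SE ≈ 0.3 percentage points), and 2000 voxels for the
null z-map rate (SE ≈ 0.005).

## Known limitations

Tractography, FEM field modeling, MRI preprocessing, registration
estimation, and ICA-based connectivity covariates are consumed as inputs
or out of scope, not computed. The ANOVA assumes a complete balanced
within-subject design and two-level factors as used here (sphericity
corrections are unnecessary with 1-df effects and are not implemented).
The percent-change effect uses sham as denominator; a difference-in-points
variant is a documented configuration away in analysis code built on the
same cells. The safety guideline is a single configurable %rMT limit, not
a full guideline table.
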