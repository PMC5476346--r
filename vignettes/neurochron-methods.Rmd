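---
title: "Methods: brain-predicted age, SRTM amyloid quantification and the association models"
author: "neurochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-predicted age, SRTM amyloid quantification and the association models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`neurochron` implements a three-part analysis used in Down syndrome (DS)
brain-ageing studies: (i) a kernel Gaussian-process (GP) regression that
predicts chronological age from voxelwise grey- and white-matter volume
maps, yielding the brain-PAD statistic (brain-predicted age minus
chronological age, in years; positive = "older-appearing" brain); (ii)
quantification of [11C]-PiB binding (BP_ND, unitless) from dynamic PET by
the basis-function simplified reference tissue model (SRTM), followed by an
SD-threshold amyloid-positivity classification; and (iii) a battery of
regression models relating brain-PAD, amyloid load and cognition
(CAMCOG/CAMDEX). A synthetic cohort generator reproduces the statistical
structure these analyses assume, so the entire pipeline is exercised by
tests without access to clinical imaging.

# Brain-age model

## Features and kernel

Each subject contributes spatially normalized GM and WM probability volumes
on a common grid. Both are smoothed with a separable Gaussian kernel
(default FWHM 4 mm; sigma per axis = FWHM / (voxel size x 2 sqrt(2 ln 2)),
truncated at 4 sigma, renormalized to unit sum, zero-padded boundaries),
flattened in fixed column-major raster order and concatenated GM-then-WM
into x_i. Only dot products enter the model, so any consistent raster order
is equivalent. The training kernel is K[i,j] = x_i . x_j. No brain mask or
feature pruning is applied by default: all voxels enter the vector (an
explicit design choice; a mask can be emulated upstream by zeroing maps).
The synthetic generator produces "volume-like" probability maps directly,
so no Jacobian modulation step exists in the package.

## Centring, normalization and the GP

`fitGPR()` double-centres the kernel, K_c = (I - 1/n) K (I - 1/n),
which is algebraically identical to removing the mean feature vector. This
is essential, not cosmetic: anatomical baselines dominate x_i, so the raw
kernel's top eigendirection is a near-constant vector carrying no age
information. With a single-start marginal-likelihood optimization the
uncentred parameterization collapses to a flat model (the optimizer shrinks
the signal variance to suppress the constant direction before it can
exploit the small age-related directions). Kernel centring is the standard
remedy in kernel neuroimaging regression and is applied here with the
centring statistics stored in the model and applied to cross-kernels at
predict time. After centring the kernel is normalized by its mean diagonal
(kernel-scale invariance).

Ages are centred on the training mean mu. The GP covariance is
sigma_f^2 K_tilde + sigma_n^2 I with a fixed diagonal jitter of
1e-8 x trace/N. Hyperparameters maximize the log marginal likelihood,
optimized by L-BFGS-B in (log sigma_f^2, log sigma_n^2) from the fixed
start (0, log var(y) / 2); the eigendecomposition of K_tilde makes each
likelihood evaluation O(n). Degenerate inputs are handled explicitly:
zero-variance ages produce a constant-mean predictor, and an identically
zero centred kernel (all feature vectors equal) does the same rather than
failing. Predictions are the GP mean,
mu + sigma_f^2 K_cross_tilde alpha with
alpha = (sigma_f^2 K_tilde + sigma_n^2 I)^{-1} (y - mu); the predictive
variance is not used.

## Cross-validation, metrics, permutation test

`crossvalPredict()` shuffles subject indices with the run seed and deals
them round-robin into k folds (default 10), so fold sizes differ by at most
one and fold membership depends only on (n, k, seed) - never on the labels.
Accuracy is summarized by Pearson's r, R^2, MAE and RMSE; R^2 is reported
as the square of r (consistent with the convention of pairing r with
"variance explained" in this literature), with the 1 - SSE/SST version
computed alongside (`r_squared_ss`).

`permutationTest()` permutes the age labels n_perm times, repeats the full
cross-validation per permutation, and reports
p = (1 + #{r_perm >= r_obs}) / (n_perm + 1), so the smallest attainable p
is 1/(n_perm + 1). By default hyperparameters are re-optimized inside every
permutation. This matters: reusing hyperparameters fitted to the observed
labels is anti-conservative under the null, because maximum-likelihood
hyperparameters adapt to spurious kernel directions correlated with the
observed labels, which permuted labels cannot exploit. The package's
calibration test demonstrates uniform null p-values under the re-optimizing
default; the fixed-hyperparameter mode remains available as a speed knob
for settings where the signal is far from the null.

# PET kinetics

## TAC extraction and partial-volume handling

`extractRoiTac()` includes voxels carrying the ROI label with GM
probability >= 0.65 (>= 0.90 for the superior-cerebellum reference via
`extractReferenceTac()`); the thresholds are inclusive at the boundary.
Each included voxel's time-activity curve is divided by (1 - CSF
probability) at that voxel *before* ROI averaging - the order matters and
is fixed, since ROI-level correction would give a different mean. Voxels
with CSF probability above 0.95 are excluded (with a logged count) rather
than divided, because division by near-zero amplifies noise. Frame weights
default to frame durations (variance-motivated; configurable per TAC).

## Basis-function SRTM

The SRTM relates a target TAC to a reference TAC:
C_T(t) = R1 C_R(t) + (k2 - R1 k2a) (C_R conv e^{-k2a t}), with
k2a = k2 / (1 + BP_ND). The basis-function scheme grids the nonlinear rate
theta3 = k2a over 64 logarithmically spaced values in [0.006, 0.6] per
minute (the standard range for PiB; configurable), computes each
convolution basis on a uniform fine grid (default step 1 s) by the exact
trapezoidal recursion y_i = a y_{i-1} + dt/2 (x_i + a x_{i-1}),
a = e^{-lambda dt}, frame-averages it, and solves the two linear
parameters by weighted least squares per grid point. The grid point with
minimal weighted residual sum of squares wins (ties resolve to the first,
i.e. smallest, theta3). Reported parameters satisfy R1 = theta1,
k2 = theta2 + theta1 theta3, BP_ND = k2/k2a - 1 by construction; negative
fitted BP_ND is allowed but flagged with a warning.

Frame averages use the half-open convention [start, start + duration).
When frame boundaries lie on the fine grid the average is trapezoidal
(second-order accurate); otherwise it falls back to a plain sample mean.
The reference curve is reconstructed from its frame averages by linear
interpolation through (0, 0) and the frame midpoints, followed by a few
fixed-point corrections that force the reconstruction's own frame averages
to match the observed TAC. The correction step removes the bias that plain
midpoint interpolation leaves wherever the curve bends inside long frames;
without it, round-trip BP_ND recovery plateaus around 2-3% error
regardless of grid density, and with it recovery is comfortably within 1%
on noiseless curves.

A note on identifiability: when the true parameters satisfy
k2 = R1 k2a exactly (theta2 = 0) the target is a scalar multiple of the
reference and BP_ND is not identifiable from the curve. Test fixtures
avoid that line in parameter space; real data sit away from it.

# Amyloid status

Striatal BP_ND is the unweighted mean over lateralized caudate and putamen
(a volume-weighted variant would require voxel counts, which the BP_ND
table does not carry). A subject is PiB-positive iff striatal BP_ND is at
least one "SD from zero". Which distribution's SD is meant is genuinely
under-determined in the source procedure, so three readings are
implemented:

* `"cohort"` (default): sigma0 = the sample SD of striatal BP_ND across
  the whole cohort. For a well-separated bimodal mixture this lands the
  threshold between the modes and classifies with high agreement to the
  generating labels.
* `"iterative"`: the self-consistent zero-anchored scheme - initialize
  sigma0 = SD of all values, classify, re-estimate sigma0 as the RMS of
  currently-negative values about zero, iterate to a fixed point (<= 50
  iterations, floor 1e-6). Its fixed point is the negative-mode SD; a
  1-sigma threshold at the negative-mode SD unavoidably flips the upper
  ~16% tail of true negatives, capping expected label agreement near 87-89%
  on the default mixture, which is why this scheme is implemented and
  exposed but not the default.
* `"fixed"`: a user-supplied sigma0, for reproducing an a-priori cutoff.

The chosen mode and the estimated sigma0 are reported in the output.
Regional abnormality applies the literal rule: per ROI, abnormal iff
BP_ND >= mean + 2 SD of the PiB-negative group; with a degenerate SD of 0,
equality with the mean still counts as abnormal. Abnormal counts are taken
over the 30-ROI catalog (20 cortical, 4 striatal, 6 other subcortical;
shipped as an editable CSV so any 30-ROI atlas can be slotted in), and mean
cortical BP_ND averages the cortical entries.

# Association models

`runAssociationModels()` fits exactly twelve documented models, in order:
brain-PAD ~ group; ICV ~ group; logistic PiB-status ~ brain-PAD + age;
mean cortical BP_ND ~ brain-PAD + age; abnormal count ~ brain-PAD + age;
CAMCOG ~ brain-PAD; CAMCOG ~ brain-PAD x PiB-status; ordinal
CAMDEX ~ brain-PAD; ordinal CAMDEX ~ brain-PAD + PiB-status;
CAMCOG ~ mean BP_ND + brain-PAD; brain-PAD ~ group on the CAMDEX-stable
subset plus controls; and the brain-PAD ~ ICV Pearson correlations per
group. Group is coded with controls as reference, so the group coefficient
is the DS - control difference (for a single binary predictor this equals
the difference of group means exactly). The sex and APOE-carrier t-tests
and the categorical Fisher tests (sex x group; the binary stable/not-stable
CAMDEX collapse against PiB status, together with the brain-PAD t-test
between those subgroups - both layouts of the under-specified collapse) are
exposed separately via `demographicTests()`.

Estimation choices: Welch's t by default (pooled-variance optional); Wald
CIs throughout for determinism (profile-likelihood CIs would be the natural
alternative for the logistic models); listwise deletion per model, so
CAMCOG models drop subjects unable to complete the assessment; raw
p-values with no multiplicity correction, mirroring the analysis style this
battery reproduces. The ordinal fits use the proportional-odds
parameterization (via `MASS::polr`); a two-level outcome is detected and
delegated to plain logistic regression, since the cumulative-logit model
with one threshold is exactly that (thresholds are reported as
`threshold: a|b` rows, and are checked to be strictly increasing).
Fisher's exact test reports the sample odds ratio ad/bc alongside the
conditional-MLE estimate, with the two-sided point-probability p.

# Synthetic cohort generator

## What it emulates

* **Tissue maps.** GM(v) = clip(g0(v) - rate x effective_age x
  pattern(v) + eps, 0, 1) with fixed smooth baseline and pattern fields;
  WM declines at half the rate under its own pattern; WM is capped at
  1 - GM and CSF fills the remainder, so per-voxel sums never exceed 1.
  Defaults: 12 x 14 x 12 voxels at 1.5 mm (the smallest grid where
  smoothing and vectorization are non-trivial while keeping kernels
  sub-second), atrophy rate 0.002 probability units per effective-age year
  at the pattern maximum (a plausible fraction-per-year scale that stays
  clear of clipping over the supported age range), per-voxel noise SD 0.02.
* **Effective age.** Chronological age (uniform 18-90 training, 28-65
  test) + an 8-year offset for DS (a realistic magnitude for the adjusted
  DS effect this design is meant to recover) + an individual brain-ageing
  deviation N(0, 5^2) years for everyone. The deviation field
  (`pad_sd_years`) is not optional plumbing: without subject-level
  brain-PAD variability the CAMCOG interaction the generator must encode
  would be unidentifiable, and prediction errors would be unrealistically
  tiny. The default 5 y sits near reported control brain-PAD SDs.
* **Head size.** A per-subject CSF scale (N(0.92, 0.04^2), clamped to
  [0.5, 1], multiplied by `csf_shrink_ds` = 0.85 for DS) gives every
  subject ICV variability and DS a reduced ICV, without touching the GM/WM
  features - so the ICV group difference cannot leak into the age model.
* **Amyloid.** Each DS subject is PiB-positive with probability 19/46;
  striatal burden is drawn from N(0, 0.05^2) (negatives) or N(0.4, 0.15^2)
  (positives) - components four mean-SDs apart, calibrated so the mean
  cortical BP_ND of positives (loading 0.9) sits near reported values.
  Non-striatal ROIs carry loading x burden only for positives; negatives
  have no specific binding outside the striatal mixture (ROI scatter SD
  0.03 about zero), matching the empirical observation that amyloid-
  negative individuals show no non-striatal abnormality.
* **TACs.** A shape-2 gamma-variate reference input (peak 300 s, analytic,
  positive, realistic early peak - chosen over a measured input function),
  SRTM forward curves with R1 = 1, k2 = 0.15/min and the subject's regional
  BP_ND, frame-averaged over the 58-frame schedule, plus Gaussian noise
  with per-frame SD = cv x value x sqrt(max duration / duration)
  (default cv 5%).
* **Cognition.** CAMCOG = 80 - 1.75 x brainPAD_true x 1[PiB+] +
  N(0, 10^2), clipped to [0, 107]; the slope default matches the magnitude
  of the interaction this design is meant to detect, and the noise SD is
  set so the interaction is detectable but not trivial at n = 46. CAMDEX
  classes are drawn with status-dependent frequencies; up to three
  dementia-class subjects are marked unable to complete the CAMCOG. APOE-e4
  carriage is Bernoulli(0.3) with 13% missingness.

## Determinism

One integer seed drives everything. Each subject draws from its own
sub-seed (seed + index for demographics and maps; seed + 100000 + index
for TACs) in a documented fixed order, so toggling map generation never
perturbs TACs, and adding subjects never perturbs earlier subjects' data.
A practical consequence for replicate studies: base seeds of successive
replicates must be spaced further apart than the subject count, otherwise
(seed, subject) pairs collide and replicates share draws. The package's
replicate-based tests stride their seeds accordingly.

## What it does not emulate

No real anatomy, registration error, scanner or motion artifacts, radio-
active decay, field-strength or site effects; PiB-positivity is independent
of age (in real cohorts positives are older); tissue "probabilities" are
volume-like by construction rather than products of an actual segmentation.
Passing tests therefore demonstrate that the estimators recover the
structure they assume, at realistic sizes and noise levels - not that the
pipeline is robust to the failure modes of real imaging.

# Problem sizes and tolerances used by the test suite

The acceptance-style tests run at the study's scale where that is feasible
in seconds-to-minutes on one CPU: the default cohort (300 training, 46 DS,
30 controls) for cross-validated accuracy; 50 seeded replicates for
offset-recovery coverage; 200 replicates of a 30-subject, 99-permutation
null for calibration; 200-500 replicates for SRTM noise robustness and
classification agreement; 400 null replicates for the interaction type-I
check. Unit tests use smaller grids (4-8 voxels per axis) and short
schedules. Numerical tolerances: exact identities at 1e-12 to 1e-8;
brute-force oracle agreement at 1e-8 or tighter; discretization-limited
comparisons (convolution against analytic forms, grid refinement) at 0.1%.

# Known limitations

* The GP hyperparameter scheme (normalized centred linear kernel, two
  variances, single fixed start) is one defensible instantiation; other
  toolboxes make different choices and will produce slightly different
  point predictions, though brain-PAD contrasts are insensitive to
  kernel scale by construction.
* R^2 is reported as r^2; for biased predictions the SSE-based version
  (also computed) can differ noticeably.
* The SRTM basis fit inherits the usual basis-function limitations: BP_ND
  resolution is bounded by the theta3 grid density, and weights are
  frame-duration based rather than count-rate based.
* `fisherExact()` reports the sample odds ratio; for tables with a zero
  cell it is infinite or undefined while the conditional-MLE estimate
  remains finite.
* The cohort-SD positivity threshold assumes the cohort actually is
  bimodal; for a cohort of near-pure negatives it will track the negative
  SD and behave like the iterative scheme.
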