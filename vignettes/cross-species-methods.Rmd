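---
title: "Methods: comparative two-species visual fMRI analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative two-species visual fMRI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xspecfmri)
```

## The problem

Two species view the same four stimulus categories — conspecific faces (CF),
conspecific occiputs (CO), heterospecific faces (HeF) and heterospecific
occiputs (HeO) — in a block design: 6 runs of 12 blocks, each block four 2-s
video clips of one category, preceded by a 10-s fixation window (a 226-s
schedule sampled as 75 volumes at TR 3.2 s). The scientific questions are
(i) whether visually-responsive cortex is organized more by the *species* of
the stimulus or by its *faceness*, (ii) whether those category distinctions
are decodable from multivoxel patterns, and (iii) whether the two species'
representational geometries correspond when conditions are matched by
stimulus identity ("direct") or by functional role, own-species to
own-species ("functional").

Conditions are stored species-neutrally (conspecific-relative), so one code
path serves both arms: arm A plays the role of the species with widespread
conspecific-preference and no face effect, arm B the species with widespread
face-preference.

## First-level model

Each condition's block onsets are convolved with the canonical double-gamma
haemodynamic response (response gamma shape 6, undershoot shape 16, ratio
1/6; the continuous kernel is peak-normalized to 1, attained at t = 5 s).
Convolution is carried out on a 0.1-s microtime grid and sampled at volume
onsets; the simulator uses the *same* routine, which makes noise-free
amplitude recovery exact and gives every downstream stage a sharp oracle.

The design matrix holds the four condition regressors, `floor(2T/128)`
discrete-cosine drift regressors (128-s high-pass; 3 columns at the default
240-s run), six mean-centered motion parameters, and an intercept.
Estimation is ordinary least squares. We deliberately do not prewhiten:
temporal autocorrelation exists only in the simulator (AR(1), coefficient
0.3 by default), and OLS keeps the estimator identical to the pseudo-inverse
oracle used in the tests. The cost is mild inefficiency of first-level
variance estimates; group inference is random-effects and does not rely on
first-level variances.

Runs are fitted separately and a subject's contrast map is the mean of its
run-wise contrasts (C>He uses weights (1, 1, -1, -1), F>O uses
(1, -1, 1, -1); equal norms, so the two betas are directly comparable).
Scans whose translation range exceeds 3 mm are excluded (strictly greater
than; exactly 3 mm keeps the run).

## Group inference

All group tests share one mechanism: one-sample statistics across subjects
with a sign-flip permutation null and cluster-extent familywise-error
correction. Suprathreshold voxels (cluster-forming threshold configurable
per arm; the per-species defaults are p < 0.001 with 4-mm spheres for arm A
and p < 1e-6 with 8-mm spheres for arm B) are clustered at 18-connectivity
(SPM-like; 6 and 26 available) and observed cluster sizes are compared with
the permutation distribution of the maximum null cluster size, with
p = (1 + #{null >= obs}) / (n_perm + 1). Sign-flipping is exact whenever
subject-level maps are symmetrically distributed about the null value,
which holds for contrast maps under no effect and approximately for
accuracy deviations from chance. Its resolution is finite: with n subjects
there are only 2^n distinct sign patterns, so the smallest attainable
voxel-level p is 2^-n — voxel-level thresholds below that are unreachable
regardless of effect size, which is why the decoding analyses ask for 8 or
more subjects.

For searchlight accuracy maps the group statistic is the voxel-wise mean
accuracy, as is conventional for decoding studies; voxel-level significance
uses per-voxel permutation quantiles, and the cluster-size null is read off
the thresholded null maps. Building the accuracy null by re-running every
subject's searchlight under block relabelling is statistically cleaner but
computationally explosive (each resample costs a full searchlight per
subject); the sign-flip null assumes only symmetry of chance-level accuracy
deviations, and the calibration experiments in the test suite show it holds
its nominal level. A relabelling-based subject-map null can still be fed in
by precomputing subject maps under shuffled labels
(`shuffle_sample_labels()`) and passing them through the same machinery.

Peak reporting uses a greedy rule: local maxima (at least as large as all 26
neighbours) are visited in descending order and any candidate closer than
16 mm to an already-accepted peak is skipped; ties break toward the smaller
linear voxel index so tables are reproducible.

## The preference statistic

Per voxel, +1 is assigned when the C>He beta is positive and exceeds the
F>O beta, -1 for the converse, 0 otherwise (ties of equal positive betas are
0). On group-level maps the counts a (conspecific-preferring) and b
(face-preferring) give the proportion a/(a+b). Inference relabels the
stimulus blocks within each run — preserving the balanced three-per-condition
design — and refits the first-level model each resample (10,000 by default).
Both the two-sided p (distance from 0.5) and the one-sided p are reported.

The null distribution of this proportion is worth understanding: a
relabelling perturbs all voxels *coherently* (the same blocks are mislabeled
everywhere), so when the seeded effect is large relative to per-voxel group
noise the null proportion becomes bimodal at {0, 1} and the test loses
power — and this ratio does not improve with sample size, because both the
relabelling component and the group noise shrink as 1/sqrt(subjects x runs).
The statistic behaves as intended in the regime where per-volume effects
are weak and reliability comes from averaging, which is also the realistic
fMRI regime. The generator's default effect amplitudes (0.2 x noise SD per
volume) were chosen to put the synthetic study in that regime, where the
conspecific-dominant arm reproduces the expected phenomenon: proportion
near 1 with permutation p below 0.01.

The group preference-map test compares each subject's label map with the
empirical mean of label maps under within-subject relabellings (100 by
default), one-tailed in each direction, with the same cluster machinery.

## Searchlight MVPA

Volumes are labelled from the HRF-convolved condition time courses: a volume
belongs to condition c when c's convolved value exceeds 50% of its own
maximum and strictly exceeds every other condition's value; transition
volumes stay unlabelled. This drops ambiguous volumes deterministically.
Each run is then linearly detrended and z-scored per voxel. Decoding pools
conditions into two tasks (F vs O; C vs He) and uses a linear SVM (libsvm
C-classification, cost 1, no internal rescaling, class weights inverse to
training frequencies) under leave-one-run-out cross-validation. The sphere
(radius 4 mm for arm A, 8 mm for arm B; 33 and 257 voxels on a full 2-mm
grid) is clipped to the mask and centers with fewer than 2 voxels are
skipped.

## Across-species RSA

Item patterns are run-wise GLM condition betas (4 conditions x 6 runs = 24
items), rescaled per voxel by the SD of its fixation-period time course
(univariate noise normalization; zero-variance voxels are floored at 1e-6
with a warning). Betas are preferred over raw time-point patterns for noise
robustness; `extract_item_patterns(noise_normalize = FALSE)` gives the raw
scale. RDMs are 1 minus Pearson correlation; comparisons use the upper
triangle excluding the diagonal. Functional matching is the identity on
conspecific-relative labels; direct matching swaps conspecific and
heterospecific. Runs correspond by index (runs are exchangeable). Chance is
modelled by re-running the searchlight at random in-mask coordinates
(n = 1000 by default). Condition-pair follow-ups correlate the 12-item
sub-RDMs of each pair (CF-CO, HeF-HeO, HeF-CF, HeO-CO) for every
cross-species subject pair, average per arm-B participant, and compare
against a label-swap null (condition labels permuted within run); effect
size is Cohen's d = (mean_obs - mean_exp) / SD_obs.

The pair simulator plants a latent 2-D condition geometry shared between a
seeded region in each arm. Because correlation-distance RDMs are blind to
pattern magnitudes, the latent points are chosen with *swap-asymmetric
angles* (the conspecific pair subtends a different angle than the
heterospecific pair); otherwise direct and functional alignment would be
indistinguishable by construction. Per-run jitter makes run pairs
informative.

## The synthetic generator, and what it does not emulate

`simulate_group()` produces, per arm: ground-truth amplitude maps, one of
six fixed randomization schedules per subject assigned round-robin (each
schedule satisfies both constraints: no condition twice within blocks 1-4,
5-8, 9-12, and no immediate repeats), per-run BOLD with drift (random
linear + slow cosine) and AR(1) Gaussian noise, random-walk motion tables,
and per-block stimulus-property tables. Arm sizes default to 20 and 30;
grids default to 16x16x10 and 24x24x12 voxels at 2 mm — a
visually-responsive cortical *patch*, not a whole brain. The dominant
preference region covers 90% of the x-extent, mirroring the near-total
dominance the proportion statistic is designed to detect; a small disjoint
slab serves as the opposite-preference candidate region and carries no
effect.

Not emulated: physiological/vascular noise structure, spatial noise
correlation from smoothing, motion-correlated artifacts, between-subject
anatomical variability, or real video stimuli (property tables stand in for
clips, though the property operators also accept frame stacks). Passing
recovery tests therefore demonstrates correctness of the estimators and
calibration of the inference under the stated noise model — not robustness
to everything real data can do.

Stimulus properties follow condition-specific normal distributions whose
default shifts mirror the pattern the control analyses probe (faces
brighter; heterospecific stimuli shifted in contrast, hue, saturation). In
deviant mode, per-block baselines are yoked across conditions within a run
and one designated block per condition and run carries the entire (tripled)
shift on every ranked property, so deviant-block removal restores exact
balance — a construction that makes the post-removal ANOVA check
deterministic. "Contribution to the visual difference" is operationalized
as the block value's deviation from the mean of the other conditions in the
same run, signed toward the condition's own mean deviation (an absolute
mode is available); hue is averaged circularly in degrees, which avoids the
359-versus-1 artifact a naive mean would produce.

## Numerical choices and problem sizes

Voxel indices are 0-based, geometry is in mm via the affine diagonal, and
spheres include their boundary. NIfTI I/O stores float64 and round-trips
bitwise. Permutation p-values always use the (1 + k)/(n + 1) form, so the
smallest attainable p is 1/(n_perm + 1). Cluster-null computation batches
all resamples into one disjoint graph and takes per-resample maximum
component sizes in a single pass.

The test-suite and acceptance-script problem sizes (grids from 6x6x2 up to
16x16x10, 2-10 subjects per arm, 500-1000 resamples) are the package's
choices for fast, reproducible desk-scale verification; every procedure
accepts the full-scale settings (10,000-resample proportion test, 1,000+
permutation cluster nulls, full grids) through its arguments. Calibration
experiments use a cluster-forming threshold of p = 0.05 so that the
max-cluster-size null is well resolved on an unsmoothed 16x16x10 grid; at
stricter thresholds suprathreshold sets on white-noise maps are so sparse
that the size distribution degenerates to {0, 1} and the test, while still
valid, becomes conservative through discreteness.

## Known limitations

No prewhitening (documented above); no spatial normalization or template
registration (the two arms are never resampled to a common space, so
across-arm voxel-count comparisons are out of scope); no random-field
theory correction; the searchlight is not optimized for whole-brain grids
(it is an R loop over centers, appropriate for region-scale masks); and the
preference-proportion permutation test inherits the bimodality caveat
described above when effects are strong relative to noise.
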