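---
title: "Reconstructing and testing feature dimension maps with spatial inverted encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and testing feature dimension maps with spatial inverted encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdmap)
```

## The scientific problem

Visual attention theory holds that the brain maintains spatial maps of
individual feature dimensions (color, motion, orientation) whose activation
is reweighted by task goals and then combined into an overall priority map.
When an observer attends the motion of a stimulus, a motion dimension map
should represent that stimulus more strongly; the open question is the
*spatial profile* of that reweighting. Under **local enhancement**, only the
map location containing the attended-dimension stimulus is boosted. Under
**global enhancement**, activation is lifted additively across the whole
map, including locations with no stimulus at all.

Univariate fMRI analyses cannot separate these hypotheses, because
averaging over a whole region discards where in the visual field the
modulation occurred. `fdmap` implements the multivariate alternative: a
spatial **inverted encoding model (IEM)** that turns multi-voxel activation
patterns into pixelized maps of the visual field, plus the disk-based
quantification and seeded permutation statistics used to compare map
activation across attention conditions, and a synthetic BOLD generator with
explicit local/global modulation regimes so that the entire analysis chain
can be validated against ground truth.

## The encoding model

Spatial sensitivity is modeled with k = 37 identical basis functions
("information channels") arrayed on a triangular (centered hexagonal) grid,
3 rings at 2.83° spacing around fixation. Each filter is a truncated raised
cosine,

$$f(r) = \left(0.5 + 0.5\cos\frac{\pi r}{s}\right)^{7} \quad (r < s;\ 0
\text{ otherwise}),$$

where $r$ is distance from the filter center and $s$ is the size constant —
the radius at which sensitivity reaches zero. Stimuli are binary contrast
masks on a pixel grid covering the circular display aperture (±9.15°);
`masks_to_channels()` projects masks onto the filters and rescales the
resulting design matrix so its maximum entry is 1.

Training (a spatial mapping task with stimuli tiling the visual field) fits
the forward model $B_1 = C_1 W$ per voxel by ordinary least squares,
$\hat W = (C_1^{\top}C_1)^{-1}C_1^{\top}B_1$; test patterns from the
attention task are inverted through
$\hat C_2 = B_2 \hat W^{\top}(\hat W\hat W^{\top})^{-1}$ and rendered back
into maps as channel-weighted filter sums. One encoding model, estimated
only from mapping data, is reused for every attention condition, so
condition contrasts are computed on identical footing. Solves use QR
factorizations with explicit condition-number checks; a design with a
never-stimulated channel fails loudly, naming the channel.

### Trial alignment

Attention-task stimuli appear at a random polar angle (5° eccentricity)
every trial, so per-trial maps must be aligned before averaging. Two
operations are provided:

* `align_trial()` rotates the filter centers at *render* time. It is cheap
  and exact when the trial angle equals the reference, but because the
  reconstruction inherits the hexagonal channel geometry, maps of stimuli
  at angles that are not symmetries of the basis agree only approximately
  after alignment.
* `align_by_refit()` rotates the filter centers *within the model*:
  weights are re-estimated under the rotated basis and the map is rendered
  on the unrotated one. For a rotation-equivariant voxel population this
  is exactly equivariant for any rotation in the symmetry group of the
  training set (multiples of 30° when the mapping grid is run at two
  30°-separated rotations), and it is what the equivariance tests use.

For disk quantification no alignment is needed at all: measuring the
screen-coordinate map at the trial's true stimulus center and at its point
reflection through fixation is identical to aligning first and measuring at
the reference location, because alignment rotates map and disk rigidly
together. The pipeline quantifies per trial in screen coordinates for this
reason.

### Quantification

`disk_mean()` averages map pixels whose centers fall strictly inside a
1.5°-radius disk (the stimulus size) at the known stimulus location and at
the opposite location (`opposite_point()`, the reflection through
fixation). Their difference, the *selectivity* (stimulus − opposite), is
invariant to map-wide additive offsets — precisely why global enhancement
leaves it unchanged while local enhancement increases it. The *attention
modulation index* (`ami()`) is the attend-motion minus attend-color
activation, deliberately not normalized by the sum because map units can be
negative. Disk membership uses a pixel-center test without area weighting;
at the default resolutions the disk means are resolution-robust to < 1%
(verified against a 10× quadrature oracle in the tests).

## Statistical framework

All tests operate on subject × condition cell means
(`subject_condition_table()`). Parametric statistics are computed in closed
form — fully-within-subject ANOVA by balanced sum-of-squares partitioning
with each effect tested against its subject-by-effect interaction
(cross-checked against `aov()`'s `Error()` strata in the tests), paired t
with $d_z = t/\sqrt{n}$, partial $\eta^2 = SS_e/(SS_e+SS_{err})$ — but
p-values come from a seeded permutation scheme: each subject's cell vector
is independently shuffled across conditions, the statistic recomputed over
1000 iterations, and $p$ taken as the proportion of null statistics greater
than or equal to the observed one (the exact proportion rule; a $(b+1)/(m+1)$
variant is available behind a flag). For paired tests the within-subject
shuffle reduces to a sign flip of the paired differences, which
`perm_paired_t()` exploits to vectorize the whole null distribution. A
single integer seed makes every analysis bit-reproducible; the caller's RNG
state is restored on exit. No sphericity correction is applied — the
permutation supplies validity. Multiple comparisons use Benjamini–Hochberg
FDR (`fdr_bh()`, delegating to `p.adjust`), error bars use the
Cousineau–Morey within-subject SEM, and `paired_t_min_n()` reproduces the
noncentral-t sample-size computation:

```{r power}
paired_t_min_n(d_z = 1.24, alpha = 0.05, power = 0.80, tail = "one.sided")
```

For multi-factor ANOVAs the omnibus shuffle permutes the full cell vector
within subject (exchangeable under the global null); factor-restricted
shuffling schemes are deliberately not implemented.

## The synthetic experiment

`simulate_dataset()` generates complete experiments with ground truth.
Voxels have compressive-spatial-summation receptive fields: an isotropic
Gaussian (peak 1) integrated under the stimulus mask, scaled by pixel area
so the drive is resolution-robust, then passed through a power law with
exponent 0.5 and a multiplicative gain. Color-map voxels get smaller RFs
(σ ∈ [0.8, 1.6]°) than motion-map voxels (σ ∈ [1.6, 3.2]°), reflecting the
much larger receptive fields of motion-selective cortex.

Task schedules mirror the study design: attention runs of 24 trials (8 per
condition — attend fixation, color, motion; 1 s cue, 0.5 s blank, 3 s
stimulus at 5° eccentricity and a random angle), ITIs drawn from the
balanced multiset {6, 7.5, 9} s (range 6–9 s, run mean exactly 7.5 s,
the only constraints stated for the design), 3 s start and 10.5 s end
blanks, total 301.5 s. Mapping runs present 43 trials (one pass through the
37-position hexagonal grid plus 6 re-drawn target trials, flagged and
excluded from model estimation) with 0.5° uniform circular jitter, the grid
rotated 30° on every other run, and ITIs in {6, 8.25} s. Mapping-run length
is derived from the realized trial timing (stimuli, ITIs, and blanks)
rather than fixed in advance, and the ITI multiset is configurable. Neural amplitudes drive
3 s boxcars at TR = 0.75 s, convolved with a double-gamma HRF (peak ~5 s,
truncated at 32 s, FFT convolution), plus i.i.d. Gaussian noise per TR.
Per-voxel variance explained is the squared correlation of the noiseless
and noisy series, and the analysis keeps voxels with ≥ 5% variance
explained.

### Modulation regimes

Attend-fixation trials are never modulated. On attend-color/motion trials,
`spatial_gain` (default 1.3) multiplies responses of voxels whose RF center
lies within 2.5° of the stimulus (the 1.5° stimulus plus RF spillover) in
both conditions — covert spatial attention, common to both. Feature
attention then differs by regime:

* **local** — `feature_gain` (default 1.1) additionally multiplies the
  spatially gated voxels whose preferred dimension is attended;
* **global** — every voxel of the attended dimension, regardless of RF
  position, is scaled by `feature_gain` (default 1.0) and shifted by
  `baseline_shift` (default 0.3): a purely additive map-wide lift, the
  canonical form of the global hypothesis.

The default gains were fixed once, before the recovery tests were frozen,
on two grounds: 10–30% multiplicative modulations are the magnitude
feature-based attention typically produces in visual cortex BOLD, and with
these values the pipeline-recovered condition-difference effect sizes fall
in the d_z ≈ 1–3 range reported for this kind of design, rather than the
implausibly clean d_z > 10 produced by stronger gains. Likewise the noise
SD (default 3, on stimulus-drive units of order 1) was chosen so that the
variance-explained distribution straddles the 5% inclusion threshold
(median ≈ 0.2, a few percent of voxels excluded), making the voxel filter
meaningful as it is for real recordings.

### Desk-scale study conditions

The recovery tests simulate 20 subjects, 200 voxels per region, 4 mapping
and 8 attention runs per subject, on a 91-pixel analysis grid — sizes at
which the full local/global dissociation is recoverable in about a minute
of compute. They verify: in the local regime the selectivity difference
between attend-color and attend-motion is significant in both regions while
the empty opposite location shows no condition effect; in the global regime
selectivity shows no condition difference while the opposite location does;
and the AMI is positive in the motion map and negative in the color map in
both regimes.

## Numerical and design choices

* **Per-voxel scaling.** The default is mean-centering each voxel within
  run. Z-scoring (available via `scale = "zscore"`) is common practice but
  interacts with condition-locked additive modulation: the within-run SD
  absorbs covariance between the stimulus response and the modulation
  timecourse, which shrinks voxels non-uniformly and injects a spurious
  condition-by-location interaction — under a purely global (additive)
  regime it can masquerade as local enhancement. Centering is affine, so
  condition contrasts pass through the linear inversion undistorted.
* **Design normalization.** One global scalar normalizes the whole channel
  design matrix to maximum 1, preserving relative trial amplitudes; a
  per-trial variant exists behind a flag.
* **Size constant.** The filter profile fixes the form but not the value of
  s; the default s = 1.25 × spacing makes neighboring filters overlap
  substantially, and s is exposed in `channel_basis()`.
* **Response windows.** Attention trials are summarized by the mean of TRs
  4.5–7.5 s after cue onset, both endpoints inclusive (5 TRs at TR 0.75 s;
  a right-exclusive variant is a flag). Mapping trials use 3.75–7.5 s after
  stimulus onset, configurable — the training-response window is not pinned
  down by the design and is the main free choice in the training stage.
  Window-averaging then inverting equals inverting per TR then averaging
  (linearity; asserted by a test), so the cheaper order is the default.
* **Permutation engine.** Mersenne–Twister with a single documented integer
  seed per test; the pipeline spawns per-test seeds from one master seed.

## What the simulator does not emulate

Noise is i.i.d. Gaussian per TR: no temporal autocorrelation, scanner
drift, physiological noise, motion artifacts, or voxel-to-voxel noise
correlations. There are no eye movements, no behavioral responses or
staircases, and no cortical geometry — voxels are abstract RF carriers, and
"regions" differ only in RF size and feature preference. Passing recovery
tests therefore show that the analysis chain is correct and that the
local/global signatures are identifiable under the stated generative model;
they do not show that real BOLD data meet those assumptions, and
autocorrelated noise in particular would widen the permutation nulls
relative to this idealization.

## Known limitations

* The IEM inversion is unregularized; it requires more voxels than channels
  and a well-conditioned weight matrix, and small voxel populations produce
  ringing in reconstructed maps. Inverting a locally boosted voxel pattern
  also leaks a small map-wide component, so even a perfectly local
  generative modulation produces a faint opposite-location effect — at the
  default study conditions this is below detection at n = 20, but it is a
  property of the method worth knowing.
* Render-side alignment (`align_trial()`) is only approximately equivariant
  off the basis symmetry group; use `align_by_refit()` when exact
  alignment matters.
* Only fully within-subject designs with 1–3 factors are supported by the
  ANOVA; there are no mixed designs, no sphericity corrections, and no
  regularized or Bayesian decoders.
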