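---
title: "Quantifying infarct border-zone microstructure with bzdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infarct border-zone microstructure with bzdti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzdti)
```

## The problem

After a myocardial infarction, the heart wall contains three microstructurally
distinct tissues: remote (essentially normal) myocardium, the dense collagenous
scar of the infarct, and a border zone (BZ) of interdigitated viable myocytes
and replacement fibrosis surrounding the scar. The BZ conducts slowly, supports
reentry, and is the substrate of many ventricular arrhythmias, so computational
models of the post-infarct heart need voxel-wise maps of where it is and how
remodeled it is.

Late gadolinium enhancement (LGE) MRI localizes scar: infarct retains contrast
and appears bright, remote myocardium stays dark, and the BZ — a partial-volume
mixture — takes intermediate signal intensity (SI). Diffusion tensor MRI
(DT-MRI) quantifies the microstructure itself through three rotationally
invariant descriptors of the per-voxel diffusion tensor $D$:

* **ADC** $= \bar\lambda = \mathrm{tr}(D)/3$ (mm$^2$/s), the overall diffusion
  magnitude; it rises as cellularity falls.
* **FA** $= \sqrt{3/2}\,\|\tilde D\|_F/\|D\|_F \in [0,1]$ with
  $\tilde D = D - \bar\lambda I$ the deviatoric tensor; it falls with fibrosis.
* **Tissue mode** $= 3\sqrt6 \det(\tilde D/\|\tilde D\|_F) \in [-1,1]$;
  $+1$ is rod-like diffusion, $0$ orthotropic (sheet-like), $-1$ planar. It
  falls with fiber disarray. For an isotropic tensor ($\|\tilde D\|_F = 0$)
  mode is undefined and reported as `NaN`; such voxels are excluded from all
  statistics.

`bzdti` implements the full analysis chain that connects the two modalities —
LGE-based segmentation of remote/BZ/infarct, registration onto the DT-MRI
frame, invariant mapping, spatial decorrelation, and distribution-free
bootstrap statistics — together with a synthetic phantom so that every stage is
testable end-to-end without animal data.

## Pipeline stages and their assumptions

### Tensor reconstruction

Tensors are fitted voxel-wise by ordinary least squares on the log-signal of
the Stejskal–Tanner model, $\ln(S_i/S_0) = -b\, g_i^\top D\, g_i$, over the six
unique components (`fit_tensor_lls()`). The default acquisition is one $b=0$
measurement plus 30 electrostatically spread unit directions at
$b = 1000\ \mathrm{s/mm^2}$ (`default_gradient_scheme()`; design condition
number 1.57). Three deliberate choices:

* voxels with $S_0$ at the noise floor or any non-positive diffusion-weighted
  sample are **masked, not clamped** — clamping before the log transform
  biases ADC;
* **no positive-definiteness enforcement** after fitting; negative eigenvalues
  from extreme noise are kept and visible downstream, matching a plain
  least-squares reading of tensor reconstruction;
* ordinary (not variance-weighted) least squares.

### LGE segmentation

Per heart, seed regions of interest in remote and infarcted myocardium provide
SI statistics (`compute_roi_stats()`), from which two thresholds follow
(`derive_thresholds()`): the infarct threshold halfway between the remote and
infarct ROI means, and the BZ lower threshold two remote SDs above the remote
mean. Classification (`classify_lge()`) uses fixed boundary conventions —
$\mathrm{SI} \ge t_{1/2}$ is infarct, $\mathrm{SI} \le t_{bz}$ is remote — the
source rules state only the levels, so the conventions are pinned here and
tested.

Label maps are moved to the DT-MRI grid by converting each label to a binary
indicator, block-averaging in the slice direction, bicubic (Keys, $a=-1/2$)
resampling in-plane, and taking the majority fraction per target voxel with
ties broken toward the more severe label (`downsample_labels()`). Refinement
(`refine_labels()`) applies two morphological rules: 6-connected infarct
components of three voxels or fewer are relabeled BZ (preserving their
intermediate-SI interpretation rather than deleting them), and BZ voxels
farther than 3 mm (Euclidean distance in mm, which reconciles "three voxels"
in-plane at 1 mm with one 3 mm slice through-plane) from surviving infarct
revert to remote. Refinement is idempotent.

### Registration

LGE and DT-MRI frames differ by a small rigid shift. Registration is
integer-voxel and translational only: the through-plane offset aligns the LV
apex of the two binary myocardium masks, then a single global in-plane
$(dx, dy)$ maximizes the summed slice-wise 2D cross-correlation
(`register_masks()`; FFT-based, search window a quarter of the grid, ties
toward the smallest shift). Label interpolation is deliberately avoided — it
would manufacture mixed classes — and residual misalignment at this scale is
sub-voxel.

### Spatial decorrelation

Neighboring voxels share microstructure, so voxel-wise invariants are not
independent samples. Within each region, the spatial autocorrelation of each
invariant map is estimated per axis (`estimate_acf()`), the correlation length
is the first $1/e$ crossing (linearly interpolated, then rounded to an integer
stride, minimum 1; `autocorrelation_length()`), and the map is decimated on a
lattice anchored at the region bounding-box minimum (`decimate()`). The
in-plane x and y axes share one rounded length, since a single in-plane value
is the natural summary; the through-plane length is rounded separately. The
$1/e$ convention is the standard correlation-length definition; note its
honest consequence below.

**A structural caveat:** samples spaced exactly at the $1/e$ crossing retain a
lag-1 correlation of about $1/e \approx 0.37$ — by definition of the crossing,
for *any* smooth autocorrelation shape. Decimation at the correlation length
therefore reduces, but does not annihilate, residual correlation; the test
suite asserts the reduction rather than pretending independence. Users wanting
stricter independence can multiply the strides.

### Bootstrap statistics

All inference is distribution-free, since invariant distributions are skewed
with unequal variances across regions:

* `bootstrap_histogram()` — 32 equal-width bins spanning the pooled range of
  two groups; 1000 resamples give a percentile 95% CI per bin; two regions
  differ within a bin when their CIs do not overlap.
* `bootstrap_median_ci()` — percentile CI of the median (1000 resamples).
  Percentile rather than BCa: the simplest construction consistent with
  "bootstrapped CIs", with measured coverage 0.92–0.98 at $n = 500$.
* `bootstrap_two_group()` — difference of medians with independent resampling
  of both groups; two-sided $p$ from the sign distribution of the resampled
  differences, floored at $1/(1+B)$.
* `bootstrap_rm_anova()` — the bootstrap analog to repeated-measures ANOVA.
  Each (heart, region) cell is summarized by its median; the observed
  statistic is the classical within-subject $F$ on the hearts $\times$ regions
  median table. The null distribution removes the region effect while
  preserving heart effects: within each cell, samples are recentered by
  subtracting the cell median and adding the heart's overall median, then
  cells are resampled with replacement and $F$ recomputed $B$ times
  ($p = (1 + \#\{F^* \ge F\})/(1+B)$). This construction is validated by its
  type-I error (0.05 $\pm$ 0.02 at $\alpha = 0.05$ over 400 null simulations
  in the acceptance tests) rather than by fidelity to any particular script,
  because "a bootstrap analog to repeated-measures ANOVA" underdetermines the
  resampling scheme.

Defaults: 1000 resamples for CIs, 10000 for tests (p-value floor
$\approx 10^{-4}$), 95% level. All routines take a seed and are exactly
reproducible.

## The synthetic phantom

`phantom_spec()` parameterizes a left-ventricular annulus (default 96 × 96 ×
16 voxels at 1 × 1 × 3 mm; inner/outer radius 18/32 mm; apex toward low slice
indices with two empty headroom slices so through-plane shifts are observable)
containing an inferior infarct wedge (90° around 270°, inner 65% of the wall,
interior slice range) and a 3 mm BZ shell around it. It emulates:

* **Region invariant distributions.** Per-region medians default to the pooled
  reference values the pipeline is calibrated against (normal
  0.563/0.470/0.743, remote 0.573/0.464/0.666, BZ 0.647/0.417/0.621, infarct
  0.797/0.330/0.515 for ADC $\times 10^{-3}$ mm$^2$/s, FA, mode). Families
  respect each invariant's support: log-normal ADC, logit-normal FA,
  clamped-normal mode, each driven by a latent Gaussian field so that the
  median maps exactly to the target. The per-region dispersion (0.15) is a
  free parameter — only medians and their CIs are published for the reference
  data — chosen as a realistic ~15% relative spread and documented as ours.
* **Spatial correlation.** Latent fields are smoothed with a separable
  Gaussian of $\sigma = L/2$ per axis, which gives a $1/e$ autocorrelation
  length of exactly $L$, then re-standardized; per-region defaults are the
  rounded lengths characteristic of ex vivo myocardium (remote 3 in-plane /
  2 through-plane voxels, BZ 1/1, infarct 2/1). Correlation is imposed on the tissue fields, not on the noise.
* **Fiber architecture.** The primary eigenvector follows a transmural helix
  from +60° (endocardium) to −60° (epicardium) — the standard ventricular
  convention; the tertiary eigenvector is radial. Eigenvector analysis is out
  of scope, so any smooth, anatomically plausible field suffices.
* **Acquisition.** DWI via the Stejskal–Tanner forward model with Rician
  noise $\sqrt{(S+n_1)^2 + n_2^2}$, $n \sim N(0, s_0/\mathrm{SNR})$, SNR 59;
  LGE at 3 × 3 × 9 upsampling (≈ 0.33 mm isotropic) with per-region normal SI
  (remote 100, BZ 160, infarct 300, SD 10), Rayleigh background at LGE SNR 10,
  and a rigid offset of the whole LGE frame (default 2, −1, 3 mm; randomized
  per heart in study runs) for registration to recover. One SNR subtlety: the
  conventional estimate "tissue mean / background-ROI SD" applied to Rayleigh
  background reads about $1.53\times$ the per-channel SNR parameter, because
  the Rayleigh SD is $\sigma\sqrt{2-\pi/2} \approx 0.655\sigma$; `compute_snr()`
  implements the conventional estimate, and the tests assert against the
  known Rayleigh moment.

What the phantom does **not** emulate: chamber-filling silicone, susceptibility
bath, coil profiles, eddy-current/EPI distortion, rotational misalignment,
non-stationary noise, or histologically realistic BZ interdigitation (its BZ
is a clean shell with its own SI and invariant plateaus). Passing tests
therefore demonstrate that the pipeline's numerics and logic recover known
ground truth under realistic noise and partial-volume conditions — not that
the segmentation thresholds would be optimal on any particular scanner's data.

## Numerical choices

* Eigenvalues from an invariant triple use the closed form
  $\tilde n = \mathrm{ADC}\cdot\mathrm{FA}\sqrt{3/(1.5-\mathrm{FA}^2)}$,
  $\theta = \arccos(\mathrm{mode})/3$,
  $\lambda_i = \mathrm{ADC} + \tilde n\sqrt{2/3}\cos(\theta - 2\pi(i-1)/3)$,
  which round-trips through the forward computation to $10^{-10}$.
* FA $=0$ makes the inverse ignore mode and return the isotropic triple.
* Connected components use 6-connectivity ("connected" is otherwise ambiguous
  in 3D); component labeling, erosion, Gaussian smoothing and bicubic weights
  are small, tested, self-contained routines.
* Degenerate inputs error early and descriptively: empty masks, overlapping
  ROIs, non-separable thresholds, collinear gradient schemes (full-spectrum
  condition number — note that `kappa(exact = TRUE)` silently drops zero
  singular values), constant regions in ACF estimation.
* All randomness flows from one root seed through named substreams (tensor,
  DWI noise, LGE noise, per-heart offsets, bootstrap), so stages can be rerun
  in isolation and whole studies are byte-reproducible.

## Problem sizes

Unit tests run on 48 × 48 × 8 phantoms; the acceptance-level tests and the
`scripts/acceptance.R` study use the native 96 × 96 × 16 grid with three
normal and up to seven infarcted hearts, a size at which the pooled regions
contribute thousands of decorrelated samples while a full study completes in
minutes on one CPU.

## Limitations

* Registration is translational integer-voxel only; rotations or deformations
  would need an external tool.
* The b0-threshold myocardium mask stands in for tensor-based segmentation; it
  is accurate on the phantom (Dice ≥ 0.95) but would be the first thing to
  replace for real data with low b0 contrast.
* The rm-ANOVA null construction is one defensible reading of a bootstrap
  analog to repeated-measures ANOVA; alternatives (e.g. residual-based
  resampling) would differ in small samples.
* Decimation at the $1/e$ length leaves ~$1/e$ residual lag-1 correlation, as
  discussed above.
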