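---
title: "Cross-contrast masked autoencoding for multi-contrast brain MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-contrast masked autoencoding for multi-contrast brain MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mcmae` is a desk-scale, fully seeded implementation of a self-supervised
pretraining strategy for multi-contrast 3D brain MRI and of the analysis
chain built on top of it: fine-tuning into a two-class discriminator for
parkinsonian-syndrome style problems, occlusion-sensitivity saliency with
group-level permutation statistics, and the evaluation layer (confusion
metrics, ROC/AUC, the DeLong paired test).  Every stage runs on a CPU in
minutes against a synthetic phantom cohort, so the whole pipeline is
testable end to end.

## The pretext task

The input is a 3-channel volume: T1-weighted, T2-weighted and FLAIR
images co-registered onto one grid, each channel min–max normalised to
[0, 1] over its non-zero (brain) voxels.  The pretext task hides random
cubic blocks of each channel and asks a U-shaped encoder–decoder to
reconstruct the full volume.  Crucially the three channels receive
*independent* mask draws: at a voxel where T1 is hidden, T2 or FLAIR is
usually visible, so minimising the reconstruction error pushes the
encoder to learn the cross-contrast relationships (how tissue classes
map to intensities in each contrast), not merely spatial inpainting.

The reference masking scheme uses `n_blocks = 84` blocks of edge 16 on a
128×128×64 grid, with block corners drawn uniformly over all
fully-inside positions.  Blocks may overlap; each block masks exactly
16³ voxels.  The sum-of-block-volumes bound on the masked fraction is
84·16³/128²·64 = 0.328; because placements concentrate in the grid
interior, the *expected* union fraction is lower
(`expected_mask_fraction(c(128,128,64), 84, 16)` evaluates the exact
separable formula and gives 0.266).  Masking roughly a third to two
fifths of the brain content keeps the recovery problem hard but solvable
from context.  The package reports both the whole-grid and within-brain
fractions (`masked_fraction()`), since the two accountings differ once a
brain mask is involved.

## The hybrid loss

For each sample, two independent channel-mask sets are drawn and the
model reconstructs both masked versions.  With `x` the original, `r_a`
and `r_b` the paired reconstructions:

* `L_recon` — the L1 loss, i.e. the mean absolute error between
  corresponding voxels of the original and the reconstruction, averaged
  over the pair: `(|r_a − x| + |r_b − x|) / 2` (means over all voxels
  and channels);
* `L_contrast` — the discrepancy between the paired reconstructions.
  The package uses the mean absolute difference `|r_a − r_b|`: it is
  symmetric, zero exactly when the pair coincides, lives on the same
  scale as `L_recon` (so the multiplicative combination below stays well
  conditioned), and needs no negative pairs;
* `L_total = L_recon · (1 + L_contrast)` — the consistency term scales
  the reconstruction loss instead of being added to it, so its gradient
  contribution vanishes as reconstructions become faithful and the total
  can never undercut `L_recon`.

`L_recon` is computed over **all** voxels, not only masked ones,
matching its definition as a mean over corresponding voxels; with the
fill value equal to the normalised background (0) the visible voxels are
nearly free to reconstruct, so the masked regions dominate the loss in
practice.

## Architecture

The encoder is a hierarchical pyramid honouring the stage-shape
contract: stage *i* (i = 0…5 in the reference profile) has spatial
shape `grid / 2^i` and `2^(j−1)·C` feature maps with `j = i` except
`j = 1` at `i = 0` (C = 24 in the reference profile).  Features pass to
a convolutional decoder through skip connections at every resolution,
and a 1×1×1 convolution with a sigmoid produces the reconstruction, so
outputs always lie in (0, 1).

The package's backbone is a plain 3×3×3 convolution + ReLU stage with
2× average pooling between stages and nearest-neighbour upsampling in
the decoder, written directly in R/RcppArmadillo with explicit
forward/backward passes.  Any hierarchical encoder honouring the
stage-shape invariant is acceptable for the pretext task; shifted-window
attention internals are out of scope here — the scientific content being
exercised is the cross-contrast masking scheme, the hybrid loss and the
statistics downstream, none of which depend on attention.  The encoder
stages are shared verbatim with the classifier, so pretrained weights
load directly (`build_classifier()`, `load_encoder_weights()`).

The test profile uses C = 8 and 3 stages on a 32×32×16 grid, the
largest configuration that keeps full training runs inside CPU-minute
test budgets; the constructors accept the reference profile unchanged
(`encoder_config(24, 5, c(128, 128, 64))`), and the shape contract is
asserted for all six reference stages.

## Training profiles

Reference-scale defaults: Adam at a fixed
1e-4 for pretraining with held-out evaluation every 5 epochs and
best-SSIM checkpointing; AdamW with cosine decay from 1e-5 to 1e-9 over
200 epochs, cross-entropy loss and best-validation-accuracy
checkpointing for fine-tuning.

The desk-scale *fixtures* keep every structural element (optimiser,
schedule shape, checkpoint rules, split handling) but pass larger
initial learning rates: 3e-3 for pretraining and 1e-3 for fine-tuning.
The reason is a step-budget argument, not tuning folklore: Adam-family
updates move each weight by at most ≈ lr per step, so a fixture run of
~10²–10³ steps at 1e-4 or 1e-5 could displace weights by at most ~10⁻²
of their initialisation scale — indistinguishable from the untrained
model — whereas the reference runs take ~10⁵–10⁶ steps.  The rates were
fixed from this argument (with 1e-2 rejected for driving the decoder
into a dead-ReLU constant-output collapse) before the acceptance
thresholds were evaluated, and are not revisited.

The classifier head is global average pooling of the deepest encoder
stage → fully-connected layer (width 128) → ReLU → 2 logits.  The
output layer starts at zero so an untrained classifier scores every
subject exactly 0.5; the positive class is the PD-like class `"A"`,
fixing the sensitivity/specificity orientation.

## The phantom cohort

No public data accompany the problem, so the package generates a
synthetic stand-in that preserves exactly the structures the analysis
needs and nothing more:

* one tissue-label map per subject — ellipsoidal grey shell, white
  core, midline ventricle, brainstem-like midline core, cerebellum-like
  posterior mass — with ±3–5 % per-seed jitter of centres and radii;
* three channels rendered from fixed lookup tables whose tissue rank
  order differs between channels (CSF dark on T1/FLAIR, bright on T2,
  …), so cross-channel context genuinely carries information; additive
  Gaussian noise (sd 0.05) on brain voxels and a smooth multiplicative
  bias field (amplitude 0.2) emulate acquisition nuisance; channels are
  then min–max normalised with background exactly 0;
* a two-class structural effect: class B dilates the ventricle and
  erodes the midline core (a midline phenotype), class A thins the
  posterior mass (a posterior phenotype).  Morphology steps scale with
  `effect_size` (`ceiling(2·effect_size)` dilation steps,
  `ceiling(effect_size)` erosion steps), every changed voxel is recorded
  in a ground-truth `lesion_mask`, and `effect_size = 0` yields
  exchangeable classes.

The default fixture uses `effect_size = 2` ("strong"), chosen as a
deliberately easy recovery problem: the acceptance question is whether
the pipeline finds a *known, large* implanted difference, not where its
detection threshold lies.  What the phantoms do **not** emulate —
anatomical realism, sequence physics, registration error, scanner site
effects, disease heterogeneity — bounds what green tests mean: they
validate the machinery (losses, training loop, statistics, FWER
control), not clinical performance.

## Evaluation protocol

Cohorts split 8:1:1 (train/validation/test) per class by a seeded
stratified draw.  At 40 subjects/class the test split holds 4 + 4
subjects, which makes an AUC quantised in steps of 1/16 — far too coarse
to distinguish "chance" from "signal" for the null-cohort check.  The
fixtures therefore score the trained classifier on an *independent
evaluation cohort* of 25 subjects/class drawn from a disjoint seed
stream: under the null the AUC's standard deviation is then ≈ 0.082, so
the chance band [0.3, 0.7] spans ±2.4 sd.  The same protocol is applied
to both the strong-effect and null arms.  The split's own test set is
still produced, used by the pipeline stage reports.

Metric reports follow the standard test-set layout: accuracy,
sensitivity, specificity, precision, F1 and AUC, with 95 % confidence
intervals from a stratified nonparametric bootstrap (case resampling
within each true class, percentile 2.5/97.5, 2 000 resamples by
default).  Metrics with zero denominators are flagged undefined, never
silently zeroed.  AUC uses the rank (Mann–Whitney) formulation with
midranks for ties; `delong_test()` implements the placement-value
(structural-component) variance estimate for paired AUC comparison, with
`z = 0, p = 1` by convention when the variance degenerates.

## Saliency statistics

Occlusion sensitivity: a cubic patch (fixture 8³, stride 4, mirroring
the masking-block/grid ratio of the reference profile's 16³ patches with
2× overlap averaging) is filled with 0 in all channels at every lattice
position; the drop in the predicted probability of the subject's true
class is accumulated per voxel and divided by the coverage count.  Maps
are computed for correctly-classified subjects only, smoothed with a
Gaussian kernel (FWHM 4 voxels, σ = FWHM/2.3548, reflective
boundaries), and compared between groups with a voxelwise two-sample
pooled-variance t statistic (the group-difference contrast of a
two-column GLM; covariates are a configuration extension, off by
default).  Zero-variance voxels yield t = 0 with a flag.

TFCE integrates cluster support over all thresholds:
`TFCE(v) = Σ_h e(v,h)^E · h^H · Δh` with the field-standard E = 0.5,
H = 2, 26-connectivity, and a midpoint discretisation into
`n_steps = 100` equal steps up to the map maximum (1 000 steps bring the
single-voxel case within 0.25 % of the closed form `h₀³/3`).  Negative
lobes are enhanced on the negated map and recombined with sign.
Family-wise error control uses the max-statistic permutation scheme:
group labels are permuted `n_perm` times, the image-wide maximum
absolute TFCE is recorded, and corrected p-values are
`(1 + #{perm max ≥ |TFCE_obs|}) / (n_perm + 1)`, so p can never fall
below `1/(n_perm+1)`; fewer than 20 distinct relabelings trigger a
warning stating the attainable minimum.  Registration to a standard
space is out of scope: phantoms share one grid, and real data are
accepted pre-registered.

## Numerical choices and degenerate inputs

* Trilinear interpolation with voxel-centre alignment for resampling
  and resizing (monotone, exact on constants); 0-based voxel indices
  internally, physical positions at voxel centres.
* Normalisation statistics over non-zero voxels only; a constant
  non-zero channel maps to 0 with a warning rather than failing.
* SSIM follows the Gaussian-weighted reference formulation (σ = 1.5,
  truncation 3.5 σ, population covariances, reflective boundaries, edge
  crop of one window radius) and matches scikit-image's implementation
  to ~5·10⁻¹¹; PSNR reports +Inf at zero MSE.
* Validation-accuracy ties during fine-tuning resolve to the earliest
  epoch; all shuffles, mask draws, subject seeds and permutations are
  hashed from user seeds (`hash_seed()`), so every run is exactly
  reproducible single-threaded.
* The pretraining-transfer check (pretrained initialisation not worse
  than scratch at epoch 1) is asserted with a documented tolerance of
  0.05 in validation cross-entropy: with 8 pretraining volumes the
  transfer benefit is within fixture-scale noise.

## Problem sizes used by the test suite

Tests and the acceptance script run the full pipeline at 32×32×16 with
C = 8: pretraining 20 epochs on 8 + 2 no-noise phantoms; fine-tuning 15
epochs on 40 subjects/class; saliency on 15 fresh subjects/class with
199 permutations; 20 seeded repetitions of the permutation test under
the class null; 1 000 DeLong null simulations; 500 bootstrap-coverage
simulations.  These sizes were chosen so each stage exercises its full
code path with non-trivial statistics.

## Known limitations

* The convolutional backbone is a stand-in profile for hierarchical
  encoders in general; no attention, no mixed precision, no GPU path.
* The phantom's two phenotypes are geometric caricatures; effect-size
  calibration against clinical data is impossible by construction and
  the parameter-recovery checks operate at a deliberately strong effect.
* `L_contrast` is one concrete reading of a reconstruction-consistency
  discrepancy; an embedding-space alternative is left as a configuration
  extension.
* The permutation-FWER null check inherits the usual discreteness of
  small-sample permutation tests: with α = 0.045 effective per
  repetition, 20 repetitions identify gross miscalibration, not small
  deviations.
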