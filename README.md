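# mcmae — cross-contrast masked autoencoding for multi-contrast 3D brain MRI

`mcmae` implements, at fully testable desk scale, a self-supervised
pretraining strategy for multi-contrast brain MRI and the analysis chain
built on it.  The intended user is a methods researcher who wants to
exercise, validate or extend the pipeline — masking pretext task, hybrid
loss, fine-tuning, saliency statistics, evaluation statistics — without
access to clinical data or GPUs.

**The core idea.**  A 3-channel volume (T1-weighted, T2-weighted, FLAIR
on one grid, each channel normalised to [0, 1]) is masked with *n* = 84
random 16³ blocks per channel, drawn **independently per channel**, and a
U-shaped encoder–decoder must reconstruct the original.  Because a voxel
hidden in one contrast is usually visible in another, the encoder is
forced to learn cross-contrast tissue relationships.  Training minimises
a hybrid loss over paired reconstructions *r<sub>a</sub>*, *r<sub>b</sub>*
of the same volume under two mask draws:

    L_recon    = ( |r_a − x|₁ + |r_b − x|₁ ) / 2        (voxel-mean L1)
    L_contrast = |r_a − r_b|₁                           (pair discrepancy)
    L_total    = L_recon · (1 + L_contrast)

The encoder stage *i* has spatial shape `grid/2^i` and `2^(j−1)·C`
channels (`j = i`, except `j = 1` at `i = 0`).  The pretrained encoder is
fine-tuned into a two-class discriminator (global average pooling → FC →
ReLU → 2 logits, cross-entropy, AdamW with cosine decay), and
occlusion-sensitivity saliency maps of correctly classified subjects are
compared between groups with a voxelwise GLM contrast, threshold-free
cluster enhancement (TFCE) and max-statistic permutation FWER control.
Reconstruction quality is scored with SSIM/PSNR; classifiers with
accuracy/sensitivity/specificity/precision/F1/AUC (stratified bootstrap
CIs) and compared with the DeLong paired AUC test.

Since no clinical data ship with the method, the package includes a
first-class synthetic cohort generator: seeded brain-like phantoms with
three contrast channels rendered from one tissue map (channel-specific
tissue contrast, noise, bias field) and a controllable two-class
structural effect (midline vs posterior phenotype) whose altered voxels
are recorded as a ground-truth lesion mask — so classifier recovery and
saliency localisation can be validated against known truth.

## Worked example

```r
library(mcmae)

# 40 subjects/class with a strong midline-vs-posterior effect
cohort <- generate_cohort(cohort_spec(n_per_class = 40, effect_size = 2,
                                      master_seed = 11))
print(cohort)
#> phantom_cohort: 40 subjects/class, grid 32x32x16, effect_size 2
#>      test train val
#>    A    4    32   4
#>    B    4    32   4

# fine-tune a classifier (desk-scale profile)
clf <- build_classifier(encoder_config(8, 3, c(32, 32, 16)), 128, seed = 1)
run <- train_finetune(clf, cohort,
                      finetune_config(epochs = 15, lr_init = 1e-3, seed = 2))
records <- predict(run$model, mcmae:::split_subjects(cohort)$test)
roc_auc(records$true_label, records$score)
#> [1] 1

# the reference worked example: metrics from test-set tallies
print(metrics_from_counts(confusion_counts(tp = 160, fn = 13,
                                           tn = 114, fp = 51)))
#> accuracy     0.811
#> sensitivity  0.925
#> specificity  0.691
#> precision    0.758
#> f1           0.833
```

The classifier reaches AUC 1.0 on the held-out phantoms because the
implanted effect is deliberately strong — the point of the fixture is
parameter recovery (a null cohort trains to chance-level AUC), not a
realistic difficulty level.  The confusion-metric block reproduces a
reference evaluation-table row from its raw tallies: 274/338 correct
(81.1 %), sensitivity 160/173 (92.5 %), specificity 114/165 (69.1 %).

The full pipeline (phantoms → pretraining → fine-tuning → evaluation →
saliency statistics) is one call with a YAML config:

```r
run_pipeline("experiment.yaml")          # or validate_config() first
```

and writes per-stage artifacts plus a `manifest.json` with content
hashes; reruns resume from existing artifacts.  A thin CLI wrapper is
installed at `inst/cli/mcmae`.

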