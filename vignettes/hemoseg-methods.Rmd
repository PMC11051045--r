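---
title: "Methods: hemorrhage segmentation with a residual U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemorrhage segmentation with a residual U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hemoseg)
```

This vignette explains the scientific model behind `hemoseg`, the
assumptions and tunable parameters of each stage, what the synthetic
phantoms do and do not emulate, and the numerical and design choices made
where the problem left them open.

## The segmentation problem

Intracranial hemorrhage (ICH) appears on non-contrast head CT as a
hyperdense (bright) region inside the skull. Clinical datasets of this
kind pair each CT volume with a radiologist-drawn binary mask (foreground
stored as 255) and label each positive slice with one of five anatomical
subtypes: epidural and subdural bleeds hug the inner skull surface as
crescents, intraparenchymal bleeds sit inside the brain tissue,
intraventricular blood collects near the midline ventricles, and
subarachnoid blood is scattered and diffuse. Subtype frequencies are
heavily imbalanced; in the cohort this package models they occur in
proportions 173:73:24:18:56 at the slice level. The task is per-pixel
binary segmentation of the merged "ICH" class.

## Slice preparation

Volumes are read from NIfTI; the slice axis is the third array axis and
slice indices are 0-based (a convention the package fixes explicitly).
Masks are validated to contain only {0, 255} or {0, 1} and binarized by
255 ↦ 1, an idempotent mapping. Only slices with a non-empty mask enter
training. Each slice is min–max normalized to [0, 1]; a constant slice
maps to all zeros rather than dividing by zero (it carries no signal).
Per-slice min–max normalization is the package's choice for single-channel
slices feeding a sigmoid-output network; an optional Hounsfield windowing
hook (off by default) is available in the CLI config for data that are not
already windowed, because the normalization choice is deliberately
recorded in the run configuration rather than hidden.

## Augmentation model

Six operators: horizontal flip, vertical flip, brightness ×1.10,
brightness ×0.90, rotation +10° (counterclockwise), rotation −5°.
Geometric operators co-transform the mask; brightness operators never
touch it. Rotation uses bilinear interpolation for the image and
nearest-neighbour for the mask (so the mask stays binary), about the
image center, zero-filled, shape-preserving. "10% brightness" is read as
multiplicative scaling with clipping to [0, 1]; an additive offset would
also be defensible, but scaling is the more common reading and the choice
is recorded here.

The per-subtype plan leaves the abundant epidural class alone, applies
all six operators to the two rarest classes (intraventricular,
subarachnoid), brightness-up + rotation +10° to intraparenchymal, and
both brightness ops + rotation +10° to subdural. This expands
173/73/24/18/56 original slices to 173/219/168/126/224. When a subtype's
plan contains both the vertical flip and brightness-down, brightness-down
is applied to the vertically flipped image (the pairing used to build the
augmented set); brightness-up always acts on the original orientation.
With that rule every per-subtype total above is reproduced exactly.
Deduplication of coincidentally identical augmented images is not
modelled: the pipeline reports per-class counts directly, which keeps the
count law (`|output| = sum over samples of 1 + |plan[subtype]|`) exact and
auditable. After augmentation all samples are relabelled to the single
"ICH" class.

## The network

The model is an encoder–decoder of the U-Net family built from residual
blocks. Each block computes `F(x) + shortcut(x)`, where `F` is three
convolution → batch-norm → ReLU stages (the third stage omits the ReLU
before the addition) and the shortcut is the identity when shapes match,
else a 1×1 projection; the first convolution of a block uses stride 2
when the block downsamples. With the default spec the encoder has four
levels with channels 16/32/64/128, so a 512² input contracts to 64² while
depth grows from 3 (grayscale replicated to three channels) to 128.

The decoder performs iterative deep aggregation: at each level an
aggregation node takes the same-level encoder map, the upsampled previous
aggregation output, and the upsampled deeper encoder map; all inputs are
resampled to the finest size (nearest-neighbour), aligned to a common
channel count by 1×1 convolutions, summed, and fused by one 3×3
convolution. The head is a 1×1 convolution to one channel with a sigmoid,
giving per-pixel probabilities strictly inside (0, 1). Two alternatives
are spec options: `plain_skip` reduces the decoder to standard U-Net
concatenation skips, and `backbone = "resnet34"` swaps the encoder for
the standard 34-layer residual layout (7×7/2 stem, 3×3/2 max pool, basic
two-convolution blocks in stages of 3/4/6/3 at 64/128/256/512 channels).
The aggregation wiring is the package's interpretation of deep-feature
aggregation in this family of networks — fuse shallow detail with deep
context at every decoder step — chosen because it is the standard
construction consistent with a residual encoder; the plain-skip option
preserves a vanilla U-Net baseline under the same training harness.

Numerical choices: 3×3 convolutions, batch normalization (momentum 0.1,
eps 1e-5, biased batch variance; inference uses running statistics),
ReLU activations, stride-2 convolution for downsampling, nearest-neighbour
2× upsampling followed by convolution, He-initialised weights under a
configurable seed, no pretraining. All of these are conventional for
residual U-Nets and are exposed through the spec rather than hard-coded
where they plausibly vary.

The network, its reverse-mode autodiff and the Adam optimizer are
implemented in the package itself (R tape-based autograd over
RcppArmadillo im2col/GEMM convolution kernels). Gradients of every layer
are verified against central finite differences in the test suite.

## Training protocol

Adam with learning rate 0.001 and batch size 16; the loss is binary
cross-entropy plus a soft Dice term. BCE is averaged over all pixels;
the Dice term is computed per sample and averaged over the batch, which
keeps its gradient informative for small lesions (a pooled Dice lets
large lesions dominate). Dice smoothing constant 1. The epoch count is
config-mandatory (no silent default protocol) with an optional
early-stopping rule on the training-loss plateau: the epoch budget is an
explicit experimental parameter, never a hidden default.

Cross-validation uses k = 10 by default: a seeded random permutation
split into near-equal folds (sizes differ by at most one), a fresh model
per fold, and per-fold metrics aggregated as mean ± population standard
deviation. Folds are drawn at the slice level, matching the protocol of
splitting labelled images; because slices of one patient are correlated,
a `by_patient = TRUE` option assigns whole patients to folds for
leakage-safe estimates. Slice-level splitting therefore tends to produce
optimistic estimates, which is precisely why both options exist.

## Metrics

Pixel confusion counts give precision, recall, F1, accuracy and
specificity; IOU is |A∩B|/|A∪B|. Conventions: two empty masks have
IOU 1 (perfect agreement), empty-vs-non-empty 0; any 0/0 metric returns
`NA` — an explicit undefined marker — never a silent 0. Object-level
detection labels 8-connected components and matches predicted to truth
components greedily by descending pairwise IOU; matches at IOU ≥ 0.5 are
true positives, unmatched predictions false positives, unmatched truth
components (missed objects) false negatives. Component-level matching is
the strictest reading of an "object detected" criterion. ROC curves pool
pixels within a fold and sweep the threshold over observed probability
values with ties grouped, making the trapezoidal AUC equal to the
Mann–Whitney rank statistic (an equivalence the tests verify to 1e-9);
the fold-set variant interpolates each fold's curve on a common grid and
reports the pointwise mean curve plus the mean of per-fold AUCs.
Subgroup reports average per-slice metrics within demographic groups
(age threshold, default 18 years, or sex) and omit empty groups rather
than reporting zeros.

## The phantom model

Phantom slices emulate the *statistical structure* of a windowed head CT
slice, not its anatomy: a bright skull annulus (intensity 0.95, radii
0.41–0.47 of the side), noisy mid-gray parenchyma (0.35, additive
Gaussian noise σ = 0.04, clipped to [0, 1]) inside it, and hyperdense
lesion blobs at +0.30 over parenchyma. Blob morphology follows the
subtypes: tangentially-oriented ellipse∩annulus crescents at the inner
skull rim for epidural/subdural, free ellipses in the central band for
intraventricular, mid-radius ellipses for intraparenchymal, and several
scattered small ellipses for subarachnoid. The mask is the exact union
of the placed blobs, and every mask pixel lies strictly inside the inner
skull radius. Blob sizes were fixed so that a lesion occupies roughly
2–8% of the brain disk; this keeps the phantom task solvable by a
threshold oracle (Otsu restricted to the skull interior reaches IOU ≥ 0.5
on well over 90% of slices), which is the calibration the synthetic task
is required to satisfy: it guarantees that a failure of the network to
learn is a defect of the pipeline, not an impossible task. Below ~2%
foreground Otsu's between-class criterion collapses onto the parenchyma
noise mode, so much smaller blobs would void that guarantee.

Cohorts mirror the real dataset's bookkeeping: one scan+mask NIfTI pair
per patient with 5 mm slice spacing in the header, masks stored as
{0, 255}, about 30 slices per scan (Poisson), an exact
`round(n_patients × ich_fraction)` count of hemorrhage-positive patients,
a contiguous block of positive slices per positive patient (Poisson mean
9, at least one), per-slice subtypes drawn from the 173:73:24:18:56
frequencies, sex drawn at the 46:36 male:female ratio and age from a
truncated Normal(27.8, 19.5²) on [1, 90]. Identical specs and seeds give
byte-identical NIfTI output.

What the phantoms do **not** emulate: Hounsfield-calibrated physics,
beam-hardening and streak artifacts, anatomical texture (ventricles,
sulci, grey/white contrast), partial-volume effects at lesion borders,
inter-rater annotation noise, and lesions near-isointense with the skull.
Passing the phantom suite therefore demonstrates that the pipeline's
mechanics — data handling, augmentation bookkeeping, optimization,
metrics — are correct and that the network can learn a solvable
segmentation task end to end; it does not certify clinical performance,
which requires real CT data at full resolution and far longer training.

## Desk-scale study conditions

The package's end-to-end training check runs at desk scale on one CPU:
side-128 phantoms, 200 training and 50 held-out slices with subtypes at
the study frequencies, the default custom residual encoder with channel
schedule 8/16/32/64, Adam lr 0.001, batch 16, BCE+Dice, 14 epochs. These
sizes are the package's chosen desk-scale analogue of the full protocol
(512² inputs, 16–128 channels, GPU training); halving the channel
schedule and fixing 14 epochs keeps one training run at a few minutes
while leaving clear headroom above the IOU 0.80 held-out target — the
run reaches held-out IOU ≈ 0.9, and the training-set IOU passes 0.9
within the same budget. The full-size spec remains the package default
for real use.

## Known limitations

* Training is CPU-bound and dense; 512² full-cohort training is out of
  desk-scale reach (the spec for it exists, the wall-clock does not).
* Augmented images that happen to coincide are counted, not deduplicated.
* Slice-level cross-validation leaks patient identity across folds by
  construction; use `by_patient = TRUE` for honest generalization
  estimates on real cohorts.
* The phantom's simplifications listed above; in particular bright skull
  adjacency is the known hard case for rim bleeds and the phantom makes
  it easier than reality.
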