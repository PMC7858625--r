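---
title: "Methods: automated inner-ear segmentation with an attention-gated 3D U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated inner-ear segmentation with an attention-gated 3D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The inner ear (labyrinth) — cochlea, vestibule and three semicircular
canals — is a small, thin, bilateral structure that appears bright on
high-resolution T2-weighted MRI of the cerebellopontine angle. Manual
segmentation takes an experienced reader on the order of ten minutes per
case and suffers from inter-observer variability; downstream applications
(3D visualization, surgical planning, radiomics, volumetry of fluid
compartments) need segmentations at scale. `otoseg` implements a fully
automated pipeline: preprocessing, an attention-gated 3D U-Net trained
with a Tversky objective, thresholded inference mapped back to the
original scan grid, and the volumetric statistics used to judge the
result.

Because clinical MRI cohorts cannot ship with a package, `otoseg` also
contains a first-class synthetic-data module that generates labyrinth
phantoms with ground-truth masks. Every stage of the pipeline is exercised
end-to-end on phantoms in the test suite.

## Preprocessing

Three steps, in this order:

1. **Isotropic resampling** to 0.45 mm voxels with cubic B-spline
   interpolation for images and nearest-neighbour for masks. The B-spline
   uses the exact interpolation prefilter (causal/anti-causal recursive
   filtering), so the interpolant passes through the original samples and
   reproduces constants. Output shape is `round(shape * spacing / 0.45)`
   with voxel centres aligned at index 0.
2. **Min-max intensity rescaling** to [0, 1] using the per-volume
   extremes. A constant volume maps to zeros with a warning.
3. **Center crop / zero pad** to a fixed 256 x 256 x 64 grid. Axes larger
   than the crop get a centered window; smaller axes are padded with
   zeros. Odd remainders place the extra voxel on the high-index side — a
   fixed, testable convention. Rescaling precedes cropping so padding
   zeros cannot perturb the per-volume minimum.

Every crop is recorded in an invertible `crop_record` (original shape,
spacing, affine; resampled shape; signed offsets). `invert_crop_pad()`
returns a prediction to the resampled isotropic grid — the **evaluation
space** — and `restore_to_original()` additionally resamples
(nearest-neighbour) back to the original grid for export. Metrics are
computed in the evaluation space: ground truth and prediction must live on
a single common grid for voxel confusion counts to be meaningful, and a
fixed isotropic spacing makes volumes in cubic millimetres directly
comparable across scanners. The crop is a pure image-center crop; no
anatomy detection is attempted (a bounding-box detector is a natural
future extension for far-off-center acquisitions).

## Network

A 3D U-Net with `depth` encoder levels (default 4). Each level applies two
(3x3x3 convolution, instance normalization, ReLU) blocks; filter counts
double per level from 16 to 128 under the defaults; 2x max pooling
contracts, transposed convolutions (kernel 2, stride 2) expand. Instance
normalization (per-sample, per-channel) rather than batch statistics suits
the batch size of two; convolutions inside normalized blocks carry no bias
because the normalization subtracts the per-channel mean, making a
preceding bias exactly redundant.

**Attention gates.** Each skip connection is scaled voxel-wise by
coefficients in [0, 1] computed by additive attention from the skip
features and the up-sampled decoder map at the same resolution:
`A = sigmoid(psi(relu(Wx x + Wg g + b)) + c)`. The gated skip is then
concatenated with the decoder features. The intermediate width is half the
skip channel count (configurable). Suppressing background regions this way
matters for a structure occupying well under 1% of the volume.

**Input image pyramid.** Downsampled copies of the input (scales 1, 1/2,
1/4 by 2x average pooling) pass through one convolution block each and are
concatenated into the first three encoder levels, so coarse context is
visible where fine structure has already been pooled away. Concatenation
(rather than addition) is used as the merge: it is the weaker assumption,
letting the following convolution learn the combination.

**Output.** A 1x1x1 convolution with a logistic activation produces a
single foreground probability per voxel; the binary decision threshold is
0.5 with ties (`>=`) assigned to foreground. The output bias is
initialized to -4 so that initial predictions reflect the
background-heavy class prior: starting near 0.5 everywhere floods the
overlap-loss denominator with false positives and stalls early gradients.
All other weights use He-normal initialization, seeded and reproducible.

The network, its backward pass, and Adam are implemented natively (C++
GEMM-based convolution kernels behind a small reverse-mode tape);
gradients are verified against central finite differences in the test
suite, both per-entry and along random directions in parameter space.

## Loss

The Tversky loss on soft predictions,

$$L = 1 - \frac{\sum p g + \epsilon}
{\sum p g + \alpha \sum (1-p) g + \beta \sum p (1-g) + \epsilon},$$

with `alpha = 0.7` on false negatives and `beta = 0.3` on false positives:
under-segmentation is penalized more than over-segmentation, which is the
right asymmetry when the foreground is three orders of magnitude rarer
than background. (Note some references attach the α/β symbols to the
opposite error types; here α always weights false negatives.) With
`alpha = beta = 0.5` the loss reduces algebraically to soft Dice — with
`epsilon` in both numerator and denominator, the Tversky form at
smoothing ε equals soft Dice at smoothing 2ε exactly, which the tests
assert. `epsilon` defaults to 1e-6 and guards empty-foreground volumes;
whether the original objective carried smoothing is not recoverable, so it
is configurable (0 gives the raw index). Batch reduction is the mean of
per-volume losses.

## Training

Adam at an initial learning rate of 1e-4, mini-batches of two volumes.
Randomly selected inputs are augmented: with probability 0.5 a flip along
the vertical in-plane axis (axis 2 of the (X, Y, Z) grid — "vertical" is
not anatomically fixed, so the axis is configurable) and with probability
0.5 an in-plane rotation about the slice axis by a uniform angle within
±15°; the image is interpolated linearly, the mask nearest-neighbour, the
same transform applied to both. At the end of each epoch the Tversky loss
and mean DSC are computed on the validation set; training stops when the
validation loss has not improved for `patience` epochs (default 10) and
the weights of the best validation epoch are returned. Data order,
augmentation draws and weight initialization all derive from explicit
seeds, so runs are bit-reproducible on a fixed BLAS/thread configuration.

## Evaluation

Per case, voxel confusion counts are converted to volumes (count x voxel
volume) and rates: DSC, TPR, FPR, FNR, FDR. Conventions: when both masks
are empty DSC is 1; a rate whose denominator is empty is reported as `NA`,
never silently as 0. Cohort summaries average the **per-case** rates and
attach t-based 95% confidence intervals (`mean ± t(0.975, n-1)·SD/√n`);
note that a mean of per-case ratios is not the ratio of mean volumes, and
the two can differ visibly in skewed cohorts. Bland–Altman agreement uses
the percentage difference `100·(PV − GTV)/mean(PV, GTV)` with limits of
agreement `mean ± 1.96·SD`, optionally excluding cases with `DSC <= 0.80`
as outliers; the ground-truth-vs-true-positive volume relation is
summarized by Pearson's r and a least-squares line.

The reader-preference statistics implement the in-silico comparison: a
participant's preference score is the percentage of cases where the
automated segmentation was chosen, tested one-sided against 50% with a
one-sample t-test. The natural pairing unit is ambiguous — per participant
(n = raters) or per rating (n = raters x cases) — so both are exposed;
they can differ by many orders of magnitude in p-value.

## The phantom generator

`generate_phantom()` builds stylized labyrinths: per side a tapering
helical tube (cochlea, 2.5 turns), an ellipsoid (vestibule) and three tori
in near-orthogonal planes (semicircular canals), mirrored about the
midline with per-case jitter in position and orientation. The image is a
smooth background texture plus a bright foreground plateau (4 background
SDs by default), modulated by a smooth multiplicative bias field (±15%)
with additive Gaussian noise. A per-case target volume is drawn from the
spec's range (default 250–550 mm^3 bilateral on the 160 x 160 x 64
default grid) and sets the geometry scale; the rasterized volume constant
was calibrated once against the voxel-count oracle. Pathology variants
drop semicircular canals and/or the vestibule on one side from both mask
and signal (post-resection anatomy), or attenuate the cochlear signal
while keeping it in the mask (altered signal intensity).

What the phantoms deliberately reproduce: sub-1% foreground fraction,
thin-tube geometry at ~0.45 mm resolution, bilateral symmetry with
jitter, bias-field and noise corruption, pathology-induced missing
components, and the anisotropic-acquisition mode (0.3 x 0.3 x 0.65 mm)
for the resampling path. What they do not: real MR physics and artifacts,
partial-volume intensity profiles, anatomical shape detail,
center-to-center protocol differences, or manual-segmentation label
noise. A model that learns phantoms demonstrates that the pipeline's
mechanics (preprocessing, gradients, loss asymmetry, early stopping,
restoration, metrics) work end-to-end; it says nothing about clinical
accuracy on real MRI.

## Desk-scale study conditions

The tests and the acceptance script train a scaled-down configuration
sized for a single CPU: depth 3, base 8 filters (8→32), 64 x 64 x 32
phantoms from `phantom_spec_desk()`. The desk-scale phantom volume range
(45–95 mm^3) keeps the foreground below 1% of the voxels on the smaller
grid — the same class imbalance as the full-scale problem. The training
demonstration uses 8 training, 2 validation and 4 held-out phantoms,
learning rate 5e-3 (appropriate for a model two orders of magnitude
smaller than the production configuration), batch 2, and 16 epochs.
Statistical calibrations use 500 replicates (confidence-interval
coverage) and 2000 simulated null studies (type-I rate).

## Numerical choices and degenerate inputs

- Convolution kernels accumulate in single precision (GEMM); everything
  else is double. Gradient checks use directional derivatives to average
  out single-precision noise.
- Instance-norm epsilon 1e-5; Tversky epsilon 1e-6 in numerator and
  denominator.
- Mask binarization of float-stored files: `>= 0.5` maps to 1, with a
  warning (matching the inference threshold's tie rule).
- Constant-intensity volumes rescale to all zeros with a warning rather
  than dividing by zero.
- Resampling uses clamped boundary handling; orientation is taken from
  the NIfTI affine and never reoriented.
- Early stopping requires strict improvement (tolerance 1e-12); ties
  count as stalls.

## Known limitations

- No DICOM ingestion (NIfTI only), no multi-channel or 4D volumes.
- No connected-component post-filtering by default (none is part of the
  method); it would be a natural option for isolated false positives.
- The pure center crop assumes the labyrinths are near the field-of-view
  center, as they are in cerebellopontine-angle acquisitions.
- Single-threaded CPU training is practical only for reduced
  configurations; the full 256 x 256 x 64 / 16–128-filter model is
  expressible but expensive without an accelerated backend.
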