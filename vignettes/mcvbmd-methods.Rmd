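---
title: "Automated metacarpal vBMD measurement: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated metacarpal vBMD measurement: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcvbmd)
```

## The measurement problem

Arthritis erodes hand bone. High-resolution peripheral quantitative CT
(HR-pQCT) can quantify volumetric bone mineral density (vBMD, in
mg hydroxyapatite per cm^3) of the second metacarpal in vivo at 82 um
isotropic resolution, but the standard workflow needs a human expert to
contour the bone slice by slice — several hundred slices per scan, tens of
minutes per patient, with known inter-operator variability that grows worse
exactly where it matters most (eroded cortical bone).

`mcvbmd` implements the fully automatic alternative as a complete, testable
pipeline: a segmentation network replaces the expert contour, and everything
around it — pre-processing, post-processing, density quantification, and the
statistics that establish whether the automatic measurement agrees with the
manual one — is reproducible code. Clinical HR-pQCT data cannot be
redistributed, so the package also contains a synthetic phantom generator
that emulates the geometry and densitometry of a metacarpal scan well enough
to exercise and validate every stage end to end.

## The pipeline

1. **Simulate / acquire.** A calibrated volume (intensities with a linear
   density calibration `density = slope * intensity + intercept`) plus, for
   training data, a slice-wise expert contour annotation.
2. **Pre-process.** Drop the slices the expert did not annotate (the
   annotation stops where the distal bone narrows); mirror left hands to a
   canonical right-hand orientation; resample to a common network shape
   (512 x 512 x 80 at clinical scale); standardize intensities with the
   *training-set* mean and variance.
3. **Segment.** A 2D U-Net applied slice by slice, or a shallow 3D U-Net
   applied to the whole volume, trained with the soft Dice loss.
4. **Post-process.** Mirror left hands back; fill interior holes (the
   density measurement requires a solid mask); resample to the original
   in-plane resolution; re-insert the dropped slices as zeros.
5. **Quantify.** D100 — the mean calibrated density over all mask voxels —
   plus per-slice cross-sectional areas and bone volume.
6. **Evaluate.** Overlap metrics against the expert mask (Dice, Jaccard,
   pixel accuracy, AUROC) and method agreement between manual and automatic
   D100 (Pearson, Spearman, ICC(2,1), Bland-Altman).

## The segmentation networks

Both architectures are built from scratch inside the package: convolution,
pooling and upsampling primitives in compiled code, a small reverse-mode
tape in R on top. No deep-learning framework is required at build or run
time, and the networks are the package's own, not wrappers.

**2D network.** A U-Net whose encoder is residual: five stages with channel
widths 64, 64, 128, 256, 512 over a 3-channel input (the grayscale slice is
replicated across the three input channels, the convention of encoders
designed for natural-image pretraining), each stage one residual
double-convolution block, 2x2 max-pooling between stages. The decoder is the
standard U-Net decoder at widths 256, 128, 64, 32, 16: nearest upsampling,
skip concatenation, double convolution; a 1x1 convolution with a sigmoid
yields per-pixel foreground probability. ReLU activations; every convolution
is followed by instance normalization (at the reference batch sizes of four
slices or one volume, instance and batch normalization are nearly the same
statistic, and the per-instance form keeps inference deterministic with no
running-state bookkeeping). Four pooling stages mean inputs must be
divisible by 2^4 — hence the explicit shape contract and error.

A full ResNet34 layer stack was deliberately not replicated: one residual
block per stage at the printed widths preserves what matters for this task
(residual encoding, depth-5 feature hierarchy, the channel progression)
while keeping the hand-written engine auditable. `pretrained = TRUE`
requests natural-image pretrained weights; because no offline source for
them exists, the builder falls back to random initialization with a warning
rather than failing.

**3D network.** Depth five, first stage two channels, width doubled per
stage (2, 4, 8, 16, 32); LeakyReLU (negative slope 0.01, configurable);
dropout with probability 0.6 in the first stage only; decoder mirrors the
encoder widths. The decoder layout and negative slope are not pinned by the
reference description, so both are exposed in `model_config_3d()` with the
defaults above.

**Loss.** Soft Dice over the whole tensor,
`1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)` with smoothing `s = 1` in
numerator and denominator (standard practice; the smoothing makes the empty
case well-defined). On binary inputs with `s = 0` it is exactly
`1 - dsc(X, Y)`, which the tests assert as a cross-module identity.

**Training.** Adam with framework-default hyperparameters; learning rate
1e-5 / batch size 4 (2D, individual slices) and 1e-4 / batch size 1 (3D,
whole volumes) at clinical scale. Splits are 70/20/10 by *floor counts*,
the remainder left unassigned by default — on a 541-case cohort this
reproduces 378/108/54 with one case aside, which is the printed-count
arithmetic, and a `to_train` policy is available. Epoch budget and early
stopping are unspecified in the reference protocol; the package defaults to
at most 100 epochs with patience 15 on validation Dice, and the checkpoint
with the best validation Dice is kept. Normalization statistics are computed
inside `train_model()` from the training split only, so leakage into
validation or test data is structurally impossible; computing stats on a
whole cohort first raises a warning.

**Scaled-down configurations are first-class.** The desk-scale experiments
in the tests and the acceptance script train a width-multiplied network
(`width_multiplier = 1/8`, about 13k parameters) on 24 phantoms of
64 x 64 x 16 voxels. In this small-width regime the Adam step size is the
rate limiter for saturating the sigmoid (the Dice loss rewards confident
probabilities long after the decision boundary is correct), so the
scaled-down protocol uses learning rate 3e-2; with instance normalization
this is stable across seeds where bare convolution stacks collapse to
all-background predictions. These problem sizes were chosen so a single CPU
core trains in about a minute; they are the package's study conditions, not
tuned quantities.

## The phantom generator

The phantom emulates what the pipeline actually depends on:

* **Geometry**: the bone is a disk swept along a gently curved axis —
  a tube with a per-slice radius profile tapering toward the distal end.
  The cortical shell is the outer annulus (`shell_thickness_mm`), the
  trabecular interior the rest. A voxel belongs to a region iff its centre
  lies inside the continuous region, so every geometric count has a
  brute-force oracle.
* **Densitometry**: three class densities (defaults 750 / 180 / 30
  mg HA/cm^3 for cortical, trabecular, soft tissue — plausible orders for
  peripheral CT of hand bones), additive Gaussian noise in density units,
  and a synthetic linear calibration. The scanner's native intensity units
  are not public; the phantom therefore defines its own invertible
  calibration and stores intensities under it.
* **Pathology**: erosions are spheres centred on the shell mid-surface that
  carve background density through the cortex. The eroded voxels stay in
  the ground-truth mask (the expert contour bridges erosions along the
  periosteal surface); what changes is the image, which is exactly the
  situation that produces holes in imperfect predictions.
* **Context**: optional distractor bones — parallel tubes with the same
  densities that must *not* be segmented. Note that a fully convolutional
  network is translation-equivariant and can only distinguish identical
  objects through their position relative to the image border; at
  desk-scale fields of view this is a hard task unrelated to the
  optimization properties under test, so the scaled-down training
  experiments default to a single distractor or none.
* **Laterality**: a left phantom is the exact column mirror of the right
  phantom generated from the same seed, giving the flip logic a bitwise
  oracle. The annotated slice range emulates the expert's distal stopping
  rule (default: the proximal 80% of slices); true epiphyseal geometry is
  not modelled because the stopping rule is the only thing downstream code
  consumes.

Default in-plane grids are 128 x 128 (10.5 mm field of view at 82 um)
rather than the scanner's 1536 x 1536; slice counts keep the clinical
200-320 range. The geometry is resolution-independent, and full-resolution
grids work where memory allows. What the phantom does *not* model: real
trabecular microstructure, scanner noise spectra, beam hardening, or motion
artifacts. Tests passing on phantoms therefore demonstrate the pipeline's
correctness and its ability to learn this class of geometry — not clinical
performance on patient data.

## Coordinate and format conventions

Voxel indices are 0-based throughout the external formats; slice ranges are
half-open `[first, last)`; polygon vertices are continuous voxel
coordinates in which integer coordinates are voxel centres. Rasterization
is strictly-inside: a centre exactly on a polygon edge is background.
`mask_to_contour()` traces the outer crack boundary (between foreground and
background voxels, vertices at half-integer coordinates), so re-rasterizing
reproduces any simply connected component exactly; interior holes are not
contoured since post-processing fills them anyway. Volumes and masks travel
as NIfTI (`.nii.gz`) or uncompressed MetaImage (`.mha`), with calibration
and annotation metadata in JSON sidecars; the proprietary scanner contour
format is replaced by a documented JSON contour format.

## Post-processing choices

Hole filling must guarantee a solid mask. The package implements it as a
bounded morphological closing (disk radius = the boundary tolerance `tol`,
default 1 voxel) followed by a slice-wise border flood fill: background
regions not connected to the slice border become foreground, border-
connected notches (erosions) stay open. On a binary mask with no companion
image, the region term of active-contour formulations degenerates and only
their morphological smoothing core acts; the bounded closing provides that
smoothing while making the operation provably monotone (output contains
input) and idempotent, and the flood fill is both the guarantee and the test
oracle. Hole topology is judged per slice in 2D, matching the slice-wise
annotation workflow. Binarization uses a strict `> 0.5` rule (a voxel at
exactly the threshold is background). Mask resampling is trilinear followed
by a 0.5 threshold — smoother boundaries than nearest-neighbour at 3x
downscale, and binarity is restored exactly.

The pre-processing order is crop, flip, resize, normalize. Flip and resize
commute; normalizing after resizing means the stored statistics describe
exactly what the network sees. Statistics are global over all voxels of the
training volumes (one mean, one variance), matching a protocol that
standardizes with "the training dataset" rather than per volume.

## Quantification and agreement

D100 is implemented as the mean calibrated density over mask voxels. A
plain summation has units of density times voxels; reporting in mg HA/cm^3
forces normalization by the voxel count, which is the only unit-consistent
reading. Per-slice areas are voxel counts times the squared voxel size;
slices with no mask voxels are excluded from the mean slice area. An empty
segmentation raises an explicit error rather than returning NaN.

Agreement between manual and automatic measurements uses Pearson and
Spearman correlations (two-sided p-values), Bland-Altman mean difference
with 1.96-SD limits of agreement, and the intraclass correlation
coefficient. The ICC variant is ICC(2,1) — two-way random effects, absolute
agreement, single measurement — because the comparison treats both pipelines
as random "raters" of the same subjects and a constant offset between
pipelines should penalize agreement. The variant is recorded in the report.

One overlap-metric subtlety is documented prominently: the Jaccard index is
implemented as `|X intersect Y| / |X union Y|`. A formula of the form
`|X.Y| / (|X| + |Y|)` — i.e. without subtracting the intersection from the
denominator — equals half the Dice coefficient and cannot reproduce
Dice/IoU value pairs like 0.972/0.943 that satisfy the standard identity
`iou = dsc / (2 - dsc)`; the package asserts that identity property-wise,
and treats the non-standard form as a transcription error rather than a
definition.

Empty-mask conventions: two empty masks score Dice = IoU = 1 (perfect
agreement on "nothing"); empty against non-empty scores 0. AUROC is the
Mann-Whitney pair statistic (ties get half credit) computed from ranks and
is undefined — an explicit error — when the reference has a single class.

## Reproducibility

Every stochastic component draws from a stream derived deterministically
from a single seed (phantom generation, cohort sampling, splitting,
initialization, batch shuffling, dropout). Rerunning a pipeline
configuration with the same seed reproduces every artifact bit for bit;
the tests assert this on the emitted vBMD JSONs. Artifacts are stamped with
a configuration hash and the seed. Stage wall-clock times are logged for
information only — runtime claims are hardware-bound and never asserted.

## Known limitations

* Phantoms are geometric idealizations; no claim about clinical data
  follows from them.
* The hand-written network engine is single-threaded R + C++; it trains
  desk-scale configurations in minutes but is not suited to 512 x 512 x 80
  clinical volumes at full width on one CPU.
* The 3D network trains end to end through the same code path as the 2D
  one but is far slower per step at equal volume size; the desk-scale
  protocols therefore exercise the 2D path.
* ImageNet-pretrained encoder weights are unavailable offline; the
  pretrained configuration runs with random initialization and a warning.
* Compartment-specific densities (Dtrab/Dcomp), microstructure indices and
  erosion volumetry are out of scope.
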