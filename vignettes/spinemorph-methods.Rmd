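---
title: "Methods: anisotropic residual U-Net segmentation and normative spine morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anisotropic residual U-Net segmentation and normative spine morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`spinemorph` implements a complete analysis chain for composed sagittal
T2-weighted spine MRI: voxel-wise semantic segmentation of vertebral
bodies (VB), intervertebral discs (VD) and the spinal canal (SC) with a
residual 3D U-Net; quality control of incoming volumes; morphometry of
the segmented structures (disc volumetry, PCA disc-plane fitting,
convex-hull paraxial canal area); and age-, sex- and height-stratified
normative reference tables with subject-versus-cohort comparison.
Because population-cohort MRI is access-restricted, the package carries
a parametric spine-phantom generator whose morphometry is known in
closed form; every stage of the pipeline is developed and validated
against it.

# The segmentation network

The network is a depth-IV 3D U-Net.  Each encoder stage is a
feature-lifting convolution followed by two residual blocks; each
decoder stage mirrors this with one residual block.  A residual block is
`out = in + F(in)` where `F` is two convolutions, each followed by a
rectified-linear activation.  There is no batch normalisation and no
dropout.  Skip connections concatenate each encoder output onto the
upsampled deeper decoder output; a final 1x1x1 convolution maps the
top decoder features to 4 classes (background, VB, VD, SC), normalised
per voxel by a softmax.

The target acquisition is strongly anisotropic: ~0.9 mm in-plane pixel
spacing against 3.0 mm slice thickness.  The kernels respect this:
depth I convolves with (3, 3, 3) kernels (slice, in-plane, in-plane),
all deeper stages convolve only within the sagittal plane with
(1, 3, 3) kernels, and down-/up-sampling by factor 2 acts on the two
in-plane axes only (max-pooling down, nearest-neighbour up).  A voxel's
receptive field therefore spans few slices but a wide in-plane
neighbourhood, mirroring the information content of the data.
In-plane patch extents must be multiples of `2^(depth-1)`.

Choices the architecture description leaves open, and what this package
does:

* **Feature counts** default to 32/64/128/256 (doubling from 32, the
  classic U-Net progression) and are a configuration field; the
  desk-scale experiments use 8/16/32/64.
* **Skip combination** is channel concatenation (classic U-Net), not
  addition.
* **Down/up-sampling operators** are max-pooling and nearest-neighbour
  upsampling; nearest-neighbour avoids checkerboard artefacts without a
  transposed convolution.
* **Background class**: the voxel classifier needs an explicit
  background channel, so the network has four output channels;
  background is excluded from all reported metrics.

The forward and backward passes are implemented in C++ (via Rcpp and
RcppArmadillo) with convolutions lowered to im2col plus single-precision
BLAS matrix products; the whole engine runs in float32, the standard
precision for this class of model.

## Initialisation

Weights are He-initialised (sd `sqrt(2/fan_in)`), biases zero.  Two
standard corrections keep the early optimisation healthy; both matter in
practice:

* the second convolution of every residual block is scaled by 0.25 at
  initialisation, so identity paths dominate and activation variance
  does not double at every block (eight blocks would otherwise inflate
  the logits by two orders of magnitude and saturate the softmax);
* the classification head is scaled by 0.1 so initial class
  probabilities are near-uniform and the first gradient steps are
  informative.

## Training

The network trains as a voxel classifier on patches sampled from the
training volumes with uniform offsets (no class-balanced sampling).  In
the source acquisition a 400x400x16 patch spans nearly the whole
composed sagittal image, so every training sample contains the spine;
to reproduce that patch-to-anatomy coverage on the smaller phantom
grids, offsets are by default drawn uniformly among those whose patch
intersects the foreground bounding box (`focus_sampling`; fully uniform
sampling remains available).  Within the admissible offsets no class is
favoured.  Volumes are
z-scored (zero mean, unit variance) before entering the network, at
training and at inference.  The loss is focal cross-entropy,

$$\mathcal{L} = \frac{1}{N}\sum_v (1-p_{t(v)})^{\gamma}\,
  \bigl(-\log p_{t(v)}\bigr), \qquad \gamma = 1,$$

with a floor of $10^{-12}$ inside the logarithm; $\gamma = 0$ recovers
plain cross-entropy exactly.  The optimiser is ADAM
($\beta_1 = 0.9, \beta_2 = 0.999$) under an exponentially decaying
learning rate.  The reference schedule mirrors the production
configuration — 400x400x16 patches, 1024 samples per epoch, 400
epochs — and is the package default (`train_spec()`); the desk-scale
profiles below use the same machinery at reduced size.

Augmentation acts in the sagittal plane only: scaling (0.9–1.1),
rotation (±10°), flips (probability 0.5), multiplicative contrast
(0.8–1.25) and Gaussian blur (σ up to 1 voxel).  Geometric transforms
are applied identically to image (bilinear) and labels
(nearest-neighbour); photometric transforms touch the image only.  The
magnitudes are configuration: the method fixes the *types* of
augmentation, not their ranges.  Every range must contain the identity.

Model selection keeps the weights with the best mean validation Dice,
evaluated on a fixed set of validation patches drawn once per run.
Validation on patches rather than whole volumes keeps the per-epoch cost
proportional to the training cost.

## Inference and evaluation

Whole volumes are segmented by tiling: tiles of the training patch size
with 50 % in-plane overlap (the slice axis is tiled without overlap),
class probabilities averaged over overlapping tiles, then a per-voxel
argmax.  Evaluation is voxel-wise precision, recall and Dice per
foreground class, reported per subject, macro-averaged over subjects
and, for transparency, also from pooled confusion counts (the underlying
study does not state which convention its table uses).  When a class is
absent from both prediction and truth all three metrics are defined as 1
and the subject is excluded from that class's average.

# The spine phantom

The phantom emulates the geometry of the composed whole-spine sagittal
acquisition: axes x (anterior–posterior) and y (superior–inferior) are
in-plane at 0.9 mm, z (left–right) is the slice axis at 3.0 mm.  A
column of vertebral-body ellipsoids alternates with disc ellipsoids
along y, separated by a clearance gap so that 26-connected components
are well defined; an elliptical tube behind them, extruded along y with
a constant cross-section, is the spinal canal; a sagittal sinusoid bends
the whole column in x.  Intensities are class means (background 30,
VB 100, VD 170, SC 240, arbitrary units) plus Gaussian noise (σ = 15 by
default), optionally smoothed in-plane for partial-volume realism.

Default structure sizes approximate a lumbar segment: VB semi-axes
(15, 11, 16) mm, disc semi-axes (15, 5, 16) mm (a ~10 mm thick disc).
All vertebrae share one size; the cranio-caudal taper of a real spine is
not modelled.  The default grid auto-fits the anatomy; the full
23-vertebra spine needs roughly 830 mm along y and therefore does not
fit a 192-voxel axis at 0.9 mm — fixed-grid profiles use a short
lumbar-like segment instead.

Because every structure is an analytic primitive, per-disc volumes
($\tfrac{4}{3}\pi abc$), per-VB volumes and the canal cross-section area
($\pi ab$, or $w \times h$ for the rectangular option) are known
exactly and serve as the oracle for the morphometry engine.

## Design of the canal cross-section

The paraxial canal area estimator is the convex hull of voxel *centres*
projected onto the disc plane.  Such a hull is inscribed: it loses up to
half a voxel around the perimeter, and along the 3 mm slice axis the
extreme voxel row can sit up to 3 mm inside the analytic edge.  For a
small cross-section this bias alone exceeds 10 %.  The phantom therefore
uses a canal that is (a) anatomically plausible and large enough for the
estimator to be accurate — semi-axes (8.1, 15.2) mm, i.e. a 16 x 30 mm
cross-section — and (b) well conditioned on the lattice: the semi-axes
sit just above integer multiples of the default spacings and the tube
centre is snapped to a voxel centre, so the extreme voxel rows always
exist.  The cross-section is *not* scaled by the covariate model: canal
dimensions correlate only weakly with body size, and a fixed
cross-section keeps the area oracle sharp across a stratified cohort.
Under 2x grid refinement the measurement error shrinks; at very fine
grids a small positive residual remains because the 3 mm-thick
projection slab flattens the sagittal drift of the curved tube into the
plane — a property of the measurement definition, not of the voxel
grid.

## Covariate model

To give the normative module a recoverable signal, vertebra and disc
sizes scale linearly with height (factor height/170 cm), male subjects
are 4 % larger, and disc thickness declines by 0.4 % per year away from
age 45.  Per-subject and per-disc lognormal jitter (sd 0.05 / 0.03 in
cohorts) adds within-cell spread; jitter draws are winsorised at ±2 sd
so that a stratified cohort can never overflow a fixed grid.  These
magnitudes are configuration that plants a clean, recoverable effect —
they are not claims about biology, and the tables built from them are
not reference values for any real population.

Stratified cohorts assign subjects round-robin over the 30 cells
(5 age bins x 2 sexes x 3 height bins), so n = 30 covers every cell
once and n = 330 puts 11 in each; covariates are drawn uniformly within
the cell (ages 20–72, heights 150–195 cm).

# Quality control

Before analysis a volume must pass the dataset rejection rules:
readable file, mutually orthogonal axes, no missing slices.  Thresholds
are package decisions (the rules themselves come with none): direction
cosines of the affine must not exceed 1e-3 in magnitude between
distinct axes, and inter-slice gaps may deviate at most 1 % from the
nominal spacing.  A single NIfTI affine cannot represent non-uniform
slice positions, so acquisition slice positions may be supplied in a
`<stem>_slices.txt` sidecar; without one, positions derive from the
affine and the missing-slice rule cannot fire.  Only the sform is
written to NIfTI headers: the qform quaternion cannot encode sheared
axes, which the QC fixtures require.

# Morphometry

Structures are instance-labelled by connected components
(26-connectivity by default — with 3 mm slices, 6-connectivity can
fragment thin structures that touch only diagonally) and named
positionally from superior to inferior: vertebral bodies C2 downwards,
discs C1/C2 through L5/S1 when the expected counts (23/24) are met.
Count mismatches flag the record and fall back to positional names; a
fragmented canal is flagged and its largest component used.

Disc volume is voxel count times voxel volume.  The disc plane comes
from a PCA of the disc's voxel world coordinates: the two leading
eigenvectors span the plane, the third is the normal (oriented toward
superior).  Canal voxels within 1.5 mm of the plane (half the slice
thickness; the quantity is configurable, the method names no number)
are projected onto the plane basis and the convex hull area of the 2D
point set is the paraxial canal area.  Reading "minimal convex hull" as
the minimal *hull* (the hull is by definition minimal), the default
measures in the single PCA plane; `search_offsets` optionally takes the
minimum over parallel planes for the alternative reading.  Degenerate
cases (fewer than 3 non-collinear points, empty slab) yield area 0 with
a flag; per-subject measurement never aborts on a degenerate instance.

# Normative tables

Subjects map to cohort cells by the stated bins.  The published height
bins ("<165, 166–175, >175") leave 165–166 cm unassigned; the package
repairs them to the half-open partition ≤165, (165, 175], >175.  Age
bins are left-closed at the .5 cuts (30.5 years falls into 30.5–40.5).
Per (cell, segment, metric) the table reports n, mean, SD and the
5/25/50/75/95 percentiles (linear interpolation between order
statistics), percentiles only for cells with at least 5 subjects.
Subject comparison reports the empirical percentile rank (mid-rank
convention for ties) and z-score within the subject's cell; an
unpopulated cell yields an explicit `no_reference` marker rather than a
fabricated value.

# Desk-scale experiment profiles

The full production schedule (hundreds of epochs over hundreds of
volumes) is far beyond a single-CPU R session, so the package defines
two reduced profiles of the same pipeline, sized so that training still
converges to high Dice on the phantom task:

* **Experiment profile** (`run_segmentation_experiment()` defaults,
  also used by `scripts/acceptance.R`): 40 phantoms of 192x192x48
  voxels (3 lumbar-sized vertebrae), split 25/10/5; features 8/16/32/64;
  96x96x8 patches; 10 epochs x 128 samples; ADAM at 3e-3 held for the
  first 40 % of the epochs, then decaying to 1e-4; focal γ = 1.
  Roughly a quarter of an hour on one CPU.
* **Test profile** (used in the test suite): 12 phantoms of 128x144x24
  voxels (2 vertebrae), split 8/2/2; features 4/8/16/32; 48x48x8
  patches; 32 epochs x 64 samples, same schedule shape.  About two
  minutes.

The learning-rate schedule is chosen hotter than the reference one
(1e-3 decaying to 1e-5) because these runs are three orders of
magnitude shorter.  The binding constraint is the rarest class: discs
are under half a percent of the voxels and are only separable as an
intensity *band* between vertebrae and cerebrospinal fluid, so they are
the last class the optimiser picks up; if the rate has already decayed
when that transition starts, the run ends with discs unlearned.
Holding the initial rate through the first 40 % of the schedule makes
the transition reliable across seeds; the decay then sharpens the
boundaries.  The rate is non-increasing throughout, and the reference
configuration (`train_spec()` defaults) keeps the plain exponential
decay.

# What phantom results do and do not show

The phantom task is deliberately easier than real spine MRI: classes
are separated by clean intensity means, boundaries are geometric, there
is no bias field, no pathology, no cranio-caudal taper, no partial
volume beyond the voxelisation itself.  Passing the phantom experiment
demonstrates that the implementation — sampling, augmentation, loss,
backpropagation, tiling, evaluation, morphometry — is correct and that
the architecture can exploit the anisotropic geometry; it does not
demonstrate clinical-grade segmentation of real data, for which the
full-scale schedule and real annotated volumes are required.

# Numerical notes

* The network engine computes in float32; losses and metrics are
  accumulated in double precision.
* Runs are bit-reproducible for a fixed seed under a single-threaded
  BLAS; a multi-threaded BLAS may reorder floating-point reductions in
  the matrix products and change results at round-off level.
* One master seed fans out to cohort covariates, per-phantom noise,
  weight initialisation, patch sampling and augmentation; phantom specs
  embed their own seeds, so any phantom regenerates bit-identically.
* Argmax ties (exactly equal probabilities) resolve to the
  lowest-numbered class, deterministically.
* Empty-denominator conventions for the metrics are stated above; the
  Dice identity `dice = 2PR/(P+R)` holds to 1e-12 on every emitted row.
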