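---
title: "Reconstructing and quantifying a virtual olfactory specimen"
author: "olfstereo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and quantifying a virtual olfactory specimen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfstereo)
```

## The problem

Serial-section fluorescence histology of the human olfactory projection
produces an ordered stack of thousands of coronal sections, each imaged in
four channels (Hoechst for nuclei, UEA1 for fucosylated cells, OMP for
mature olfactory sensory neurons, VGLUT2 for their axon terminals) at about
1.1 µm in-plane and 10 µm between sections. Turning that stack into numbers
— structure volumes, the total number of olfactory sensory neurons (OSNs),
glomerulus estimates — requires three computational stages: semantic
segmentation of each section, registration of the sections into a coherent
3D volume, and a stereological quantification chain. `olfstereo` implements
all three at desk scale, together with a synthetic "virtual specimen" whose
exact ground truth makes every stage testable without any imaging data.

## The virtual specimen

`phantom_config()` + `make_phantom()` + `render_sections()` build a
miniature en-bloc specimen containing the six structures the real workflow
segments: nasal epithelium (a band of configurable thickness), OSNs
(contiguous column patches inside the epithelium), an olfactory bulb
(ellipsoid), glomeruli (a shell inside the bulb), vasculature (tubes with a
sinusoidal drift, never intersecting the epithelium), and a bone plate.
Channels are weighted sums of structure intensities under a configurable
stain matrix, plus clipped additive Gaussian noise.

Rendering then applies the artifacts that registration must undo:

* a **per-section smooth deformation**, drawn as a 4×4 grid of control
  displacements bounded by `deform_amplitude` (default 1.5 px) and
  interpolated with cubic B-splines — B-spline weights form a partition of
  unity, so the bound is exact;
* a **"banana" curvature**, a rigid lateral shift of `banana_curvature ·
  i²` px at section `i` (default 0.001 px/section²), the minimal model of a
  curved specimen that pairwise registration artificially straightens;
* **section dropout**, i.i.d. Bernoulli at `dropout_rate` (default 0.358,
  the fraction of cut sections the real study could not incorporate); a
  clustered variant is available but off by default.

Geometry is specified in micrometres and does not rescale with the grid;
small test grids therefore use a coarser pixel (2–6.5 µm) so the same
anatomy fits the field of view. Defaults (1.097 µm pixels, 10 µm sections)
match the scanning geometry of the real material.

What the phantom deliberately does **not** emulate: staining chemistry,
folds and bright-stripe scanning artifacts, the patchy "archipelago"
topography of aged human olfactory epithelium, and single-OSN texture.
Passing tests therefore demonstrate the correctness of the algorithms under
known geometry and noise, not performance on cadaveric data.

## Segmentation

One independent U-Net per structure (`build_unet()`): three encoder levels
of two 3×3 convolutions each (8/16/32 features) with batch normalisation
and 0.2 dropout before each 2×2 max pooling; a 64-feature bottleneck with a
2×2 transpose convolution; a mirrored decoder with skip concatenations; a
3×3 output convolution to two classes under softmax; ReLU activations
throughout. The implementation is self-contained (compiled convolution,
pooling and transpose-convolution kernels; analytic backpropagation checked
against numerical gradients in the test suite) and deterministic under a
fixed seed in single-threaded use.

Training (`train_unet()`) follows a staged schedule of strictly decreasing
learning rates (default 1e-4 → 5e-5 → 1e-5, 35 epochs each; the olfactory
bulb uses two stages of 200 epochs on fourfold-downsampled input). Batches
are random tile crops, each augmented by one uniform offset per channel in
[−0.01, +0.01] so the network learns relative rather than absolute
intensity. At each stage end, the best validation-Dice weights seed the
next stage. The binarisation threshold is chosen afterwards as the grid
value (default 0.01…0.99 in steps of 0.01) maximising validation Dice, ties
to the smallest cut-off.

Two conventions the architecture description leaves open were resolved as
follows: the overlapping-tile "centre pixels" rule is applied at inference
assembly only (training uses full tiles for the loss), and the Dice of two
empty masks is defined as 1 so structure-free sections are not penalised.
At inference, `tile_and_assemble()` steps tiles by `tile_size − 2·margin`
and splits each overlap at its midpoint, so every pixel is predicted
exactly once and a translation-invariant model produces a seam-free map.

## Registration

Registration is Dice-guided and block-wise. All choices are driven by the
combined mask `X^c = X^v ∨ X^e` (vasculature OR nasal epithelium), the two
most longitudinally continuous structures.

1. **Blocks.** Included sections are partitioned into contiguous blocks of
   five (the last keeps the remainder). Within each block the reference is
   the section maximising the summed pairwise Dice of combined masks (ties
   to the lowest index).
2. **Pair registration.** Every other block member is registered onto the
   reference: a rigid (or translation-only) stage, then a cubic B-spline
   free-form refinement, both multiresolution. Similarity is mutual
   information averaged over the four channels, computed with
   partial-volume (linearly weighted) histograms — hard binning makes MI
   peak artifactually at integer shifts. The coarsest level starts from an
   exhaustive integer-translation search, which fixes the capture range.
   A mask-based B-spline refinement on the combined masks follows, with a
   deliberately shallow (three-level) pyramid so it focuses on small
   structures; the refined field is kept only if the combined-mask Dice
   does not decrease, so this step can never undo the intensity stage.
   Channels are warped bilinearly and masks by nearest neighbour, each
   exactly once with the final composed field.
3. **Interfaces.** For consecutive blocks the most similar cross pair
   (exhaustive over ≤25 pairs, lexicographic ties) is registered, giving
   the interface field φ. The sections spanning the interface receive
   linear fractions of φ — the `(i−1)/N` ladder exposed as
   `interblock_interpolate()` — read from the moving-section side, and the
   blocks themselves keep their frames. This is the one point where the
   implementation deliberately departs from propagating the full φ to the
   moving section and its posterior block-mates: chaining full interface
   alignments anterior→posterior re-aligns every block to the first and
   straightens a genuinely curved specimen — precisely the banana effect
   the block design exists to avoid. With anchored blocks the curvature
   survives as a staircase with smoothed seams; the test suite shows the
   reconstructed bulb centreline tracks the programmed quadratic offset
   several-fold better than naive section-to-section registration of the
   same stack.

Pyramid depths default to 4/4/3 (rigid/B-spline/mask) and are capped so the
coarsest level keeps at least 16 px per side: on desk-scale images, levels
beyond `log2(min dimension)` are meaningless, while the configuration still
accepts the deep settings a full-resolution run would use. Similarity
evaluation uses all pixels (no random sampling), so block results are
deterministic and independent of processing order.

## Morphometry

* **Volumes** are voxel counts times the voxel volume (pixel² × thickness).
  Non-included sections get the linear interpolation of the nearest
  included neighbours; boundary gaps use the nearest included value. The
  interpolation is exact for constant and linear area profiles, which is
  why the interleaved-sampling error (`interleaved_error()`, every 4th /
  16th / 32nd section) vanishes for constant-area phantoms.
* The **envelope** of the olfactory epithelium intersects the OSN mask with
  the epithelium, expands it across the full apical–basal thickness of its
  epithelium component (per connected component, per column), and closes
  the holes in-plane with a disk structuring element (default 80 µm,
  similar to the epithelium thickness; dilation then erosion, with zero
  padding wide enough to keep the closing extensive at borders). Gaps
  smaller than the element close; a 200 µm gap survives.
* **Counts.** Manual per-section OSN counts are Abercrombie-corrected by
  `T/(T+D)` (`D` = mean nuclear diameter, a required user measurement; the
  correction is the classical factor, and `D = 0` is appropriate for the
  synthetic counts, which are free of profile splitting). Linear density
  (per mm) divided by thickness and section depth (both in mm) gives the
  volumetric density; its SEM uses Fieller's theorem for the ratio
  (SEM = interval width / 2z), with the first-order delta formula as a
  labelled alternative — the two agree to first order as the input SEMs
  shrink, a property the tests check numerically. Totals multiply density
  by the envelope volume (treated as fixed) with a delta-method 90%
  interval at z = 1.645.
* **Sphere-model glomeruli** divide a glomerular volume by the volume of a
  sphere at a stated mean diameter; the cube of the radius makes the count
  strongly diameter-sensitive, which the ratio reports make explicit.

On synthetic specimens with a programmed linear density, the pipeline's
total-OSN interval covers the programmed density × envelope volume in ≥85%
of seeded replicates (nominally 90%; the only noise source is the Poisson
variation of the simulated counts, thickness and envelope being measured
exactly on ground truth).

## Problem sizes and numerical choices

The test suite exercises the pipeline at phantom scales of 64–128 px and
6–30 sections, trains the network for ~10 epochs on four 128-px sections
(held-out Dice ≥ 0.8 for the high-contrast vasculature analog), and runs
registration with shallow pyramids; these sizes were chosen so the whole
suite runs on a single CPU in minutes while every algorithmic path is
covered. Other conventions: 32 intensity bins (reduced automatically on
small pyramid levels so histograms stay populated); Nelder-Mead for the
rigid stage and BFGS with numerical gradients (step 0.1 px) for B-spline
control points; He initialisation; Adam with β = (0.9, 0.999); ε = 1e-5
batch-normalisation; channels stored as 32-bit float TIFF pages (round
trips are exact at float precision); z fixed at 1.645 for all 90%
intervals.

## Limitations

Training at full slide scale (20k-px sections), GPU execution, Neuroglancer
precomputed output, automatic left/right or septal/lateral splitting, and
counting individual glomeruli or OSNs from masks are out of scope; manual
counts and split label images are inputs, not outputs. The registration
engine is a compact reimplementation suited to desk-scale images, not a
drop-in replacement for a production elastix pipeline.
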