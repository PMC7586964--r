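---
title: "Registering prostate whole-mount histology to MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering prostate whole-mount histology to MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After radical prostatectomy the resected gland is fixed, sectioned into
serial whole-mount slides, stained and digitized. Mapping the cancer
annotated on those slides back onto the patient's presurgical T2-weighted
MRI gives voxel-level ground truth for radiology — but histologic processing
rotates, shrinks and shifts every section independently, and the slides are
only approximately in correspondence with the MRI slices. `rapsreg`
implements the full correction pipeline and a digital phantom that makes its
accuracy measurable, because on real patients no voxel-level ground truth
exists.

The pipeline has three steps, each a 2D problem (slice-to-slice
correspondence is taken as given, from the sectioning protocol or an
expert):

1. **3D histology reconstruction.** The middle slice anchors the stack;
   every other slice is rigidly registered, walking outward, to its
   already-aligned neighbour. This undoes per-slice mounting rotation and
   translation relative to the stack without inventing out-of-plane
   transforms.
2. **Per-slice MRI alignment.** Each MRI slice is registered to its
   reconstructed histology slice: first an affine transform driven only by
   the binary prostate masks (sum of squared differences), then a free-form
   cubic B-spline deformation driven by Mattes mutual information between
   the histology luminance and the MRI intensities. Both stages run over a
   three-level multi-resolution pyramid with shrink factors 16/8/4 and
   Gaussian smoothing sigmas 4/2/1 pixels. The affine stage uses gradient
   descent (initial step 0.01 in scaled parameter space, 250 iterations per
   level); the deformable stage uses L-BFGS-B with 10 iterations per level.
3. **Label mapping.** A composite of the three transforms projects cancer
   labels, urethra masks and landmarks from histology into MRI coordinates
   in a single resampling pass (nearest-neighbour for labels, bilinear for
   images), so interpolation blur is never compounded.

All coordinates are physical millimetres; images carry their pixel spacing
and no operation interprets pixel indices as lengths.

## Transform conventions

Every stored transform is a *resampling map*: it takes fixed-image
coordinates to moving-image coordinates, so `warped(x) = moving(T(x))`. The
per-slice chain stores

* `rigid` — reconstruction frame → original slice coordinates;
* `affine`, `field` — reconstruction (histology) frame → MRI coordinates,
  evaluated as `p -> affine(p + u(p))` with `u` the B-spline displacement.

Mapping a histology *point* to MRI is therefore a closed-form forward
evaluation (invert the rigid analytically, then apply field and affine).
Warping a histology *image* onto the MRI grid needs the opposite direction:
the affine is inverted analytically and the B-spline map `p + u(p)` by
fixed-point iteration (tolerance 0.04 mm ≈ 0.1 pixel, 50 iterations cap);
points where the iteration fails are flagged and dropped with a warning.
Round-trip error on registered phantoms is checked in the test suite at
0.2 pixel.

## Why the affine stage starts from a rigid fit

A plain gradient search over the full affine group can trade rotation for
shear: for a near-elliptical mask, a small shear of the unrotated shape
overlaps a rotated shape almost as well as the true rotation, and at coarse
pyramid levels (heavy smoothing) the two solutions become indistinguishable.
The affine stage therefore first solves rotation + translation over the
same pyramid and schedule, then refines the full six-parameter affine from
that initialization. Both mask stages use analytic gradients of the SSD
through the bilinear interpolant, and a step-adaptive descent: the step
starts at the configured learning rate, grows 1.2× on accepted moves and
halves on rejections (rejected moves still consume an iteration; descent
stops early only when the step underflows, which is numerically equivalent
to idling for the remaining iterations).

Neither stage ever returns a transform that *worsens* prostate-mask
agreement: if the optimized Dice falls below the pre-registration value the
identity is returned with a warning attribute.

## The deformable stage and its guards

The Mattes formulation bins the fixed image hard and spreads each moving
sample over four histogram bins with a cubic B-spline Parzen window, which
makes mutual information differentiable in the moving intensities. The
gradient with respect to the control-point displacements is analytic
(chain rule through the bilinear interpolant and the separable tensor-product
basis) and is verified against finite differences in the unit tests.

Free-form fields driven by histogram similarity have a known failure mode on
images with little texture: small wiggles that sharpen the joint histogram
without improving anatomical alignment. Three mechanisms keep the field
honest, reflecting the requirement that it stay stiff rather than elastic:

* a bending-energy penalty on the control grid (mean squared second
  differences, weight 1 by default);
* box bounds of ±10% of the image width on every control displacement,
  enforced inside L-BFGS-B;
* two do-no-harm guards evaluated at the finest level: if the field fails to
  improve MI over the affine-only baseline, or worsens the warped
  prostate-mask Dice, the identity field is returned (with a warning
  attribute).

On the piecewise-constant phantom the injected artifacts are similarity
transforms, the affine stage recovers them almost exactly, and the guards
frequently leave the deformable stage at identity — which is the correct
answer there. The MI machinery itself is exercised directly by the unit
tests (gradient correctness, improvement on misaligned pairs, stability
under synthetic smooth warps); its clinical value lies on textured
multimodal data that the phantom deliberately does not emulate.

The control mesh is 6×6 cells at the coarsest level and doubles per level
(6/12/24); finer levels are initialized by evaluating the coarser field at
the new control nodes. The B-spline is cubic; MI uses 32 bins with the
moving range padded by two bins so the Parzen support never leaves the
histogram.

## The digital phantom

The phantom supplies paired MRI and histology with known ground truth. A
shared analytic anatomy is rasterized on the MRI grid (0.4 × 0.4 × 4.0 mm,
256², 6 slices by default):

* **gland** — a tapered solid whose axial outline is a polar curve
  `r(phi) = r0 f(z) (1 + 0.14 cos 2phi + 0.20 sin phi + 0.14 cos phi +
  0.10 sin 3phi)`. The low-order asymmetries (fuller posterior, lateral
  imbalance) matter: prostate sections are not ellipses, and it is exactly
  this asymmetry that makes mounting rotations identifiable from a binary
  mask. The gland centre sits 0.3 slice thicknesses off the stack midplane
  so apex/base taper is visible for any slice count;
* **peripheral zone** — the posterior band between the outline and the same
  outline scaled to 72%;
* **urethra** — a thin tube (radius ≈ 1.2 mm at default scale) drifting
  0.12 mm laterally per mm of z;
* **cancer** — an ellipsoidal focus (6.5 × 5 mm in-plane) in the left
  posterior gland.

Labels are exclusive with precedence urethra > cancer > peripheral zone >
prostate. The MRI fills each region with a constant intensity (bright
peripheral zone, dark cancer, T2-like), the histology with a constant
H&E-like RGB triple; both get i.i.d. Gaussian noise, 4.5 intensity units by
default (5% of the prostate/background MRI contrast — the study that the
phantom emulates does not state a noise magnitude). Histology is generated
on the MRI slice grid so the zero-artifact registration is exactly the
identity, a clean test anchor.

Artifacts are then injected per slice: rotation drawn uniformly from
[-r, r]; isotropic shrinkage to scale (1 − s) about the slice centre;
translation drawn independently in x and y up to 5% of the image width —
applied only when s > 0, matching the study design in which rotation-only
experiments carry no translation; optionally a left-right flip. Images are
resampled once from their noiseless originals and noise is re-drawn.
Imperfect slice correspondence is modelled by rasterizing the histology
anatomy 2 mm away along the slice axis — a pure out-of-plane offset; no
additional in-plane shift is implied.

What the phantom does *not* emulate: histological texture (glands, nuclei),
staining variability, tissue tearing, stitching artifacts of pseudo-whole
mounts, endorectal-coil deformation. Passing the phantom study therefore
demonstrates recovery of similarity-type processing artifacts under the
stated noise, not performance on real stained tissue.

## Evaluation metrics

* **Dice** — per-slice overlap `2|A∩B|/(|A|+|B|)` of the prostate masks,
  averaged over slices. A slice with both masks empty counts 1 (vacuous
  agreement keeps the average defined on tapered end slices); empty on one
  side only counts 0.
* **Hausdorff (mm)** — per slice, the classic symmetric max-of-sup-infs
  between the 4-connected boundary pixel centres of the two masks, averaged
  over slices. The slice-average reading (rather than a max over slices)
  matches the per-case values the metric is reported as; a percentile
  variant is deliberately not used.
* **Landmark (mm)** — mean Euclidean distance between centres of mass of
  name-matched landmarks (on the phantom: cancer and urethra centres per
  slice).
* **Urethra deviation (mm)** — centre-of-mass distance averaged over the
  slices where the urethra is visible in both modalities; others are
  excluded.

Rotation recovery is measured by polar-decomposing the linear part of the
composite histology→MRI map and comparing its rotation angle with the
negated injected angle; scale recovery compares `sqrt(det)` with
`1/(1 − s)`.

## Problem sizes and runtime

The recovery experiments in the test suite run the full study conditions
(256², 6 slices) for the rotation (r ∈ {5, 10, 15, 20}°, 10 repetitions
each), shrinkage (s ∈ {0.05, 0.10}, 10 repetitions) and imperfect
correspondence (2 mm, r ∈ {0, 10, 20, 30}) sweeps. The full 48-condition
grid (r ∈ {0…30} × s ∈ {0…0.2} × offset ∈ {0, 2}) runs at 128² with 4
slices and 3 repetitions, a deliberate scale-down that preserves the
per-condition trends; `summarize_experiment()` emits the per-condition
means and variances. A single 256² case registers in a few seconds on one
CPU core.

## Known limitations

* The reconstruction is strictly 2D rigid; torn or missing sections and
  out-of-plane bending are out of scope.
* Slice correspondence, gross rotation and flips are inputs, not estimated.
* The deformable stage is conservative by design; large elastic
  deformations (severe coil compression) would need a looser bending weight
  and displacement cap than the defaults.
* Mask-driven rotation recovery degrades as the gland outline approaches an
  ellipse; this is a property of the data, not the optimizer.
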