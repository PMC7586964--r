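# rapsreg

Registration of serial whole-mount prostate histopathology to T2-weighted
MRI, with a digital phantom for validating the recovery of
histologic-processing artifacts.

## The problem

Whole-mount histology after radical prostatectomy is the ground truth for
prostate cancer extent, but the slides it produces are individually rotated,
shrunken and shifted by fixation, sectioning and mounting, and correspond
only approximately to the MRI slices acquired before surgery. To project
cancer outlines from the slides onto MRI — e.g., to build labels for
radiologic models — each histology section must be registered to its MRI
slice and the processing artifacts undone.

`rapsreg` implements the three-step pipeline:

1. **3D reconstruction** of the histology stack: the middle slice is fixed
   and every other slice is rigidly registered outward to its
   already-aligned neighbour (transforms `T_rig` per slice).
2. **Slice registration**: each MRI slice is aligned to its reconstructed
   histology slice by a masked affine registration (sum of squared
   differences between binary prostate masks, gradient descent, 250
   iterations/level) followed by a free-form cubic B-spline deformable
   registration (Mattes mutual information, L-BFGS-B, 10 iterations/level),
   both over a three-level pyramid (shrink 16/8/4, smoothing sigma 4/2/1
   px).
3. **Mapping**: the composite `T_rig ∘ T_aff ∘ T_def` projects cancer
   labels, urethra masks and landmarks onto the MRI grid in one resampling
   pass.

Accuracy is quantified by the slice-averaged Dice overlap of the prostate
masks, the slice-averaged boundary Hausdorff distance (mm), and the
centre-of-mass deviations of landmarks and the urethra (mm).

Because no voxel-level ground truth exists for real patients, the package
ships a **digital phantom**: a synthetic prostate anatomy (gland,
peripheral zone, urethra, cancer) rendered as paired region-mean-filled MRI
and RGB histology with Gaussian noise, into which per-slice rotations
(uniform in [-r, r]), shrinkage (scale 1-s), random translations (up to 5%
of image width) and a 2 mm out-of-plane correspondence offset are injected
with known ground truth.

## Worked example

```r
library(rapsreg)

# phantom with per-slice rotations drawn from [-20, 20] degrees
spec   <- phantom_spec(max_rotation_deg = 20, seed = 42)
ph     <- generate_phantom(spec)
chains <- register_case(ph$mri, ph$stack)
report <- evaluate_phantom_case(ph, chains)
print(report)
#> registration metrics over 6 slices:
#>   Dice (input/affine/final): 0.954 / 0.993 / 0.993
#>   Hausdorff: 0.52 mm  urethra: 0.21 mm  landmarks: 0.20 mm
#>   max |angle error|: 2.05 deg
```

Reading: the corrupted stack starts at Dice 0.954 against the MRI; the
pipeline recovers the injected rotations to ≈2° or better and restores the
prostate overlap to 0.993, with the mapped cancer/urethra centres of mass
landing within a quarter of a pixel (0.4 mm pixels) of their true MRI
positions. On a zero-artifact phantom the whole chain is the identity
(Dice 1 within resampling error).

Condition sweeps:

```r
res <- run_phantom_experiment(
  list(phantom_spec(max_rotation_deg = 10), phantom_spec(shrink_factor = 0.1)),
  n_reps = 10)
summarize_experiment(res)   # per-condition means and variances
```

A thin command-line wrapper is installed with the package
(`system.file("scripts", "rapsreg", package = "rapsreg")`) with subcommands
`phantom`, `register`, `evaluate` and `experiment`; cases on disk use NIfTI
for volumes, PNG for histology slices/labels and JSON for the
correspondence table and transforms.

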