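---
title: "Hybrid registration and dose fusion: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid registration and dose fusion: models, parameters, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A course of radiotherapy for locally advanced cervical cancer combines
external-beam radiotherapy (EBRT) with high-dose-rate brachytherapy (HDR-BT).
Each fraction is planned on its own CT with its own dose grid, so the total
dose a structure receives can only be judged after mapping every fraction's
dose into one reference frame and summing voxelwise:

D_total(x) = D_ref(x) + Σ_i D_i(T_i(x)),

where T_i maps a reference-frame point x to its corresponding point in
fraction i. The quality of the accumulated dose therefore reduces to the
quality of the deformable registration producing T_i. Two properties of the
HDR-BT CT make that registration unusually hard: the brachytherapy
applicator induces large, spatially local anatomical deformations (most
visibly a repositioning of the thighs), and it scatters bright, unevenly
distributed voxels through the image that corrupt intensity statistics.

`rtfuse` implements the full chain: preprocessing, closed-form point-set
fits, intensity-driven linear and free-form registration, a
landmark-constrained free-form phase for the locally large deformation, dose
warping and accumulation — and a synthetic pelvic phantom with known ground
truth against which every stage is validated.

## Transform model

All transforms map points of the target (EBRT, reference) frame into the
source (HDR-BT) frame — the pull-back convention, so warping evaluates the
transform at reference voxel centres and samples the source there. The
composite model is additive:

T(x) = T_global(x) + Σ_k u_k(x),

with T_global rigid or affine and each u_k the displacement field of a
B-spline free-form deformation (FFD): a uniform lattice of control points
with spacing δ whose coefficients are world-space displacements in mm. The
displacement at x is the cubic B-spline tensor-product sum over the 4×4×4
control neighbourhood. Composition (T_local ∘ T_global) is deliberately not
used; the additive form is what the multi-phase strategy below assumes, and
it lets a later phase be frozen on top of an earlier one without
re-parameterization.

Lattices always cover the whole target domain plus a one-spacing margin, so
every domain point has a full neighbourhood. Points outside the covered
support get zero displacement.

### The ROI-constrained, landmark-driven FFD (LFFD)

For the locally large "thigh" deformation, intensity-driven optimization
alone tends to stall in local minima. The LFFD phase instead fits an FFD
directly to user-placed landmark pairs P (target) and Q (source): minimize

mean_i | p_i + u(p_i) − q_i |² + ridge · |Φ_free|²,

where only control points near the region of interest (ROI) are free — a
node is free iff its position lies in the ROI dilated by one control
spacing, because nodes just outside the box still influence interior voxels.
The objective is exactly quadratic in the free coefficients, so it is solved
in closed form by the normal equations rather than iteratively. The ridge
(default 1e-6) handles the usual underdetermined case of few landmarks and
many free nodes by selecting the minimum-norm interpolant; it is the one
numerical safeguard the fit needs.

Two evaluation modes exist for ROI lattices. The literal piecewise
definition (identity outside the ROI box) is available as
`strict_piecewise = TRUE`, but it makes the displacement discontinuous at
the ROI boundary, which is unacceptable for warping dose. The default smooth
mode evaluates the spline everywhere: since frozen nodes keep zero
coefficients, the displacement decays continuously and reaches exactly zero
beyond two control spacings outside the free region.

The LFFD runs coarse-to-fine (40 mm control spacing, halved twice), each
level fitting the residual landmark error of the previous; in practice the
40 mm level already interpolates exact correspondences, and the finer levels
matter when landmarks disagree with a coarse field.

## Similarity and optimization

The default similarity metric is normalized mutual information,
NMI = (H(A) + H(B)) / H(A,B), computed from a 64-bin equal-width joint
histogram with hard assignment, entropies in nats. NMI is bounded in [1, 2],
equals 2 when either image determines the other and 1 under independence.
SSD, Pearson correlation, mutual information, joint entropy and the
correlation ratio are also available; polarities are normalized internally
so one maximizer serves all metrics. During optimization the histogram
ranges are frozen per resolution level (target range and source-volume
range, both stationary) so the objective cannot drift as the warp changes.

Optimization is deterministic gradient ascent with step halving: steps along
the max-norm-normalized gradient are accepted only if they strictly increase
the objective; a rejected step halves the step length; termination on step
underflow, a gain below `tol`, or `max_iter`. A computed gradient direction
is reused for up to ten accepted moves before a fresh gradient is taken — a
pure runtime optimization that preserves determinism and monotonicity. A
steepest-ascent variant with golden-section line search is provided.

For FFD coefficients the NMI gradient uses central finite differences with
local support: perturbing one control point only moves the samples of voxels
within two control spacings, so only their joint-histogram contributions are
updated, with entropy sums maintained incrementally. The result equals full
recomputation (tested to 1e-10); the cost drops from O(N) to O(support) per
coefficient. Defaults: finite-difference step h = 0.5 mm, initial step 0.4 ×
control spacing for FFD and 1 mm-equivalent for linear parameters (rotations
and matrix entries are scaled so one optimizer unit moves the image
periphery by about 1 mm).

Multi-resolution: a Gaussian pyramid (σ = 1 voxel, ×2 decimation), three
levels by default. The FFD control spacing starts at 20 mm on the coarsest
level and halves per finer level via dyadic B-spline subdivision, which
carries the displacement field across levels exactly.

## The multi-phase strategy

`register_multiphase()` chains the phases the way a clinical run would:
coarse linear initialization (point-based rigid where intensity-based
initialization would fail, otherwise intensity-based rigid/affine), the
LFFD landmark phase with its lattice frozen afterwards, then intensity FFD
optimizing a fresh all-free lattice on top. Freezing phase 1 keeps the
landmark correction intact — the additive two-term local model — instead of
letting the intensity term dissolve it.

## Dose accumulation

Dose grids are read from DICOM RTDOSE (pixel values × dose-grid scaling,
per-frame offsets honored) or NIfTI. `warp_dose()` resamples a fraction dose
through a transform onto the reference geometry with linear interpolation
and 0 Gy outside the source footprint; `accumulate_dose()` is an exact
voxelwise sum and refuses grids that do not share the reference geometry
(no silent resampling). This is pointwise resampling of physical dose:
energy/mass-preserving dose warping and radiobiological (EQD2) conversion
are deliberately out of scope.

## The phantom: what it emulates, what it does not

`make_phantom()` builds a stylized pelvis as an analytic intensity function:
a soft body ellipsoid, a bright pelvic ring, bladder/rectum/tumor blobs and
two lateral thigh cylinders. The ground-truth transform is sampled from the
seed: global rigid/affine motion (rotations ~1.5°, translations ~3 mm,
scalings ~2%), a smooth background FFD (default amplitude 4 mm), and a
large FFD confined to a thigh ROI (default 12 mm) realized as a coherent
per-leg displacement weighted by thigh membership — emulating the leg
repositioning that makes the clinical problem hard. The source image is the
anatomy function evaluated directly; the target is the anatomy composed
with the truth transform, so both are free of interpolation error and the
truth maps target landmarks onto source landmarks exactly. Applicator-like
noise is added as positive impulses (≥ 3× tissue maximum) inside a central
tube of the source. Amplitude scaling is exact: coefficients are rescaled so
the maximum sampled displacement equals the requested amplitude.

Landmarks are placed as two rings of four points plus an axis end per thigh
(inside the ROI), the spread a user marking a 3D structure would produce; a
single line of axis points was found to leave the LFFD unconstrained
off-axis.

What the phantom does not emulate: CT noise texture and partial-volume
effects, HU calibration, the applicator's geometry (only its bright-voxel
artifact), sliding interfaces, and intensity differences between scans.
Passing the phantom suite therefore demonstrates correct mechanics and the
qualitative method ordering under known ground truth — not clinical-grade
accuracy on real data.

## Validation protocol and problem sizes

The test suite validates each operation against independent brute-force
oracles (naive tensor-product sums, per-voxel sorts, loop histograms,
normal equations assembled by hand) and then runs three phantom studies,
sized to keep a complete run on one CPU comfortably inside half an hour:

* dense-field recovery: one 64³ phantom (2.5 mm voxels) with a smooth 4 mm
  deformation; FFD registration must recover the field to a sub-voxel mean
  error inside the body;
* method ordering: ten 48³ phantoms (3 mm voxels) with affine global motion,
  4 mm background and 12 mm thigh deformation plus impulse noise; mean CC
  must order no-registration < affine < FFD ≤ LFFD+FFD, and the multiphase
  thigh-region field error must beat FFD alone in at least 8 of 10 seeds
  (it does in 10/10 here);
* denoising effect: the same ten seeds run with and without median
  filtering; the denoised runs must win on CC in at least 8 of 10 (10/10
  here).

Registration in these studies uses 8 optimizer iterations per level — the
point where the studies' quality criteria are met with time to spare; more
iterations buy small CC gains.

## Numerical choices and edge cases

* Continuous voxel indices are 0-based, voxel centres; world frame is LPS mm
  (NIfTI RAS affines converted on read/write).
* Interpolators: nearest, trilinear, Catmull-Rom ("C1-spline"), cubic
  B-spline kernel (smoothing), Lanczos-3 windowed sinc. Outside the closed
  voxel-centre hull every interpolator returns the pad value (default:
  source minimum; 0 Gy for dose).
* NMI degenerate cases: both images constant is an error (all entropies 0);
  one constant image gives exactly 1; identical images exactly 2.
* The median filter uses edge replication; radius 1 (3×3×3) by default —
  large enough to remove isolated applicator impulses, small enough to
  preserve edges. Denoising is applied after resampling in the pipeline.
* Reorientation supports direction matrices related by signed axis
  permutations (lossless voxel shuffles); oblique direct registration is
  out of scope and refused with an error.
* The Jacobian-determinant summary (`jacobian_min`) is reported, not
  enforced; diffeomorphism constraints and inverse transforms are out of
  scope.
* Transform files are JSON with base64 float64 coefficients, so round-trips
  are bit-exact; dense fields export as 4D NIfTI vector volumes.

## Known limitations

Registration assumes axis-aligned (reoriented/resampled) inputs. The DICOM
reader covers the explicit-VR little-endian profile the package's tests
exercise, not the breadth of clinical DICOM. The LFFD trusts its landmark
correspondences; there is no outlier weighting. Histogram binning is hard
(no Parzen windows), so the NMI objective is piecewise constant at the bin
scale and gradients rely on finite differences crossing bin edges.
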