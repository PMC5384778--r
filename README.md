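# rtfuse

Hybrid image registration and dose accumulation for paired radiotherapy CT
volumes, aimed at combined external-beam radiotherapy (EBRT) and
high-dose-rate brachytherapy (HDR-BT) courses — for medical-physics and
image-analysis workflows that need the dose of every treatment fraction
mapped into one reference frame and summed.

The accumulated dose is the voxelwise sum

> D_total(x) = D_ref(x) + Σ_i D_i(T_i(x)),

so everything rests on the deformable transform T_i from the reference
(EBRT) frame into each fraction's (HDR-BT) frame. The HDR-BT CT is hostile
to registration: the brachytherapy applicator induces a large, spatially
local deformation (the thighs reposition) and scatters bright impulse-like
voxels through the image. `rtfuse` addresses both with a multi-phase
strategy:

1. **Preprocessing** — reorientation, resampling onto the target grid, and
   median filtering to suppress the applicator's bright-voxel artifact.
2. **Coarse linear registration** — closed-form point-set fits (orthogonal
   Procrustes rigid, least-squares affine) from manual landmarks, or
   intensity-driven rigid/affine optimization over a Gaussian pyramid.
3. **LFFD** — a landmark-driven B-spline free-form deformation whose free
   control points are restricted to a region of interest: minimize
   `mean_i |p_i + u(p_i) − q_i|² + ridge·|Φ|²` in closed form, correcting
   the locally large deformation that defeats intensity-only methods.
4. **Intensity FFD** — multi-resolution B-spline FFD maximizing normalized
   mutual information, NMI = (H(A)+H(B))/H(A,B), with the LFFD lattice
   frozen underneath (the transform model is additive:
   `T(x) = T_global(x) + Σ_k u_k(x)`).
5. **Dose fusion** — fraction doses (DICOM RTDOSE or NIfTI) warped through
   the final transform and accumulated voxelwise.

A synthetic pelvic phantom generator with known ground-truth deformations
(`make_phantom()`) makes the whole chain testable without clinical data.

## Worked example

Register a phantom pair with the full multi-phase strategy and accumulate a
brachytherapy-like dose onto a uniform reference field:

```r
library(rtfuse)

ph  <- make_phantom(seed = 42, size = 48, spacing = 3)   # known ground truth
tgt <- median_denoise(ph$target)                         # EBRT-like, fixed
src <- median_denoise(ph$source)                         # HDR-BT-like, moving

aff <- register_linear(tgt, src, "affine", reg_config(max_iter = 15))
fit <- register_multiphase(tgt, src, ph$roi,
                           ph$landmarks_target, ph$landmarks_source,
                           reg_config(control_spacing0 = 40, pyramid_levels = 3,
                                      init_transform = aff$transform),
                           reg_config(max_iter = 8))
warped <- warp_image(src, fit$transform, tgt)
report <- evaluate_registration(tgt, warped, transform = fit$transform)

ref_dose <- make_dose(ph, "uniform")     # 2 Gy reference field
total <- accumulate_dose(ref_dose,
           list(warp_dose(ph$dose_source, fit$transform, ref_dose)))
```

Output of this exact script:

```
CC before registration: 0.940
landmark error: 5.73 mm -> 9.1e-10 mm after LFFD
NMI: 1.474 -> 1.744
CC after LFFD+FFD: 0.992 (min Jacobian 0.76)
accumulated dose: mean 2.15 Gy, max 8.93 Gy
```

Reading: the phantom pair starts at Pearson correlation 0.940 after affine
initialization would leave residual soft-tissue mismatch; the LFFD phase
interpolates the thigh landmarks essentially exactly (10⁻⁹ mm residual), the
intensity FFD raises NMI from 1.47 to 1.74, and the final correlation of
0.992 with a positive minimum Jacobian determinant (0.76, no folding) is the
registration quality the dose mapping inherits. The accumulated dose is the
2 Gy reference field plus the warped 7 Gy-peak fraction blob (max 8.93 Gy
where they overlap).

A command-line interface wraps the same functions
(`system.file("cli", "rtfuse", package = "rtfuse")`): subcommands
`preprocess`, `reg-points`, `reg-image`, `warp`, `dose-accumulate`,
`phantom`, `evaluate` and `pipeline` (flat `key = value` parameter files,
JSON reports, reproducibility manifest).

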