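---
title: "Voxel-wise aortic reverse-flow mapping: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise aortic reverse-flow mapping: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revflow)
```

## The method

4D flow cardiovascular MRI acquires a time-resolved, three-directionally
velocity-encoded volume covering the thoracic aorta. `revflow` quantifies
*retrograde* flow voxel by voxel: at every voxel of a static aortic
segmentation, velocity is projected onto the local vessel axis, its negative
part is integrated over a cardiac window, and the result is expressed as a
volume (mL per window) carried backwards — towards the aortic valve — by a
single 1 mm³ voxel.

The pipeline, given a velocity field $v_i(t)$ (mm/s), a binary lumen mask and
two seed voxels:

1. **Isotropic resampling.** Velocity components and magnitude are resampled
   trilinearly, the mask by nearest neighbour, to 1 mm isotropic resolution.
   World coordinates (voxel-centre convention) are preserved, so anisotropic
   acquisitions are handled before any geometry is computed.
2. **Preprocessing.** Classical corrections for the main phase-contrast
   error sources: temporal velocity unwrapping of venc aliasing, static
   tissue detection from magnitude and temporal velocity stability, a
   least-squares linear (or constant) fit of the residual phase offset over
   static tissue subtracted from every frame, and a magnitude-quantile noise
   mask.
3. **Geometry.** A centerline is extracted as the distance-transform-weighted
   shortest path between the seeds, smoothed and resampled at 1 mm arc
   length. One orthogonal analysis plane is placed at every centerline point;
   its unit normal $\hat n_k$ (the local tangent, oriented away from the
   valve) defines forward flow, $-\hat n_k$ reverse flow. Every mask voxel is
   assigned to the Euclidean-nearest plane. Four landmark planes — the
   sinotubular junction, proximal to the first supra-aortic branch, distal to
   the left subclavian artery, proximal to the celiac artery — split the
   vessel into ascending aorta (AAo), arch and descending aorta (DAo);
   voxels proximal to the first or distal to the last landmark are excluded.
4. **Phase windowing.** The mean net-flow curve
   $Q(t) = \overline{s_i(t)}\,a$ over the whole segmentation (with
   $s_i = v_i \cdot \hat n$, face area $a = 1$ mm²) is lightly smoothed
   (moving average, width 3). Peak systole is its earliest maximum; end
   systole is the first frame after the peak at which the discrete second
   difference turns non-negative after being negative — the discrete
   inflection point. Only frames fully inside the common 600 ms window are
   analysed: $n_{inc} = \min(n_{frames}, \lfloor 600/\Delta t\rfloor)$.
5. **Integration and statistics.** Per voxel,
   $R_W = \sum_{t \in W} \max(0, -s_i(t))\,a\,\Delta t$ (and the analogous
   forward quantity), in mL, for the systolic window (frames before end
   systole), the diastolic window (end systole onward) and the whole included
   cycle. Segment means ± SD, sagittal mean-intensity projections, a
   clinical-context total through a circular mid-ascending ROI
   ($\pi (d/2)^2 \bar R$), and Bland–Altman agreement statistics complete
   the outputs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `target_mm` | 1 mm | analysis grid spacing; the per-voxel unit of all maps |
| `mag_quantile` | 0.6 | magnitude quantile above which a voxel counts as tissue for the static mask |
| `std_threshold_mms` | 20 mm/s | maximum temporal SD of speed for "static" |
| `noise_quantile` | 0.1 | magnitude quantile below which voxels are flagged as noise |
| `eddy_order` | 1 | order of the spatial phase-offset fit (0 = constant, 1 = linear) |
| `smooth_sigma_mm` | 1.5 mm | Gaussian bandwidth for centerline smoothing |
| `window_ms` | 600 ms | common cardiac window shared by all subjects |
| `es_curve` | `"whole"` | net-flow curve used for end-systole detection |

The static-tissue and noise thresholds are engineering defaults (the
corrections they feed are standard, but no canonical threshold values exist);
both are exposed in `preprocess_flow()`. End-systole detection deliberately
uses the *whole-aorta* curve: an AAo-only curve is distorted by regurgitant
diastolic flow and can select wrong time points; the AAo variant remains
available via `es_curve = "aao"` for comparison.

## The synthetic phantom

`phantom_spec()` parameterizes a candy-cane aorta: a straight ascending limb,
a semicircular arch and a straight descending limb, all of tube radius $R$,
with exact analytic centerline and tangents. Lumen voxels carry the axial
velocity

$$u(\rho, t) = U(t)\,\mathrm{profile}(\rho/R)
  \;-\; A_{ring}\,\mathbf 1[\rho/R \ge \rho_0]\,\mathbf 1[t \in T_{ring}]
  \;-\; A_{reg}\,\mathbf 1[t \in T_{reg}]$$

along the local tangent, where $U(t)$ is a raised-cosine ejection
($P/2\,(1-\cos 2\pi t/T_{es})$ for $t < T_{es}$, zero after) and the profile
is parabolic ($1 - (\rho/R)^2$) or plug. The two reverse components emulate
the two clinical phenotypes: a near-wall systolic retrograde ring
(stenosis-like eccentric flow with recirculation) and a uniform diastolic
regurgitant plug. Both have closed-form reverse-flow integrals
(`analytic_reverse_flow()`), verified in the tests against independent
numerical quadrature. A hollow high-magnitude shell at 2–3 radii provides
realistic support for the static-tissue fit, and `inject_artifacts()` adds
spatially linear phase offsets, Gaussian velocity noise and venc wrapping.

Default study conditions (used throughout validation): 64 × 64 × 96 voxels at
1 mm, 15 frames at $\Delta t = 40$ ms, venc 150 cm/s, $R = 9$ mm, ascending
40 mm, arch radius 16 mm, descending 50 mm, peak 1000 mm/s,
$T_{es} = 360$ ms. The disease components, when enabled, use
$A_{ring} = 500$ mm/s over frames 3–6 ($\rho_0 = 0.6$) and $A_{reg} = 60$
mm/s over frames 10–15. These magnitudes are physiologically plausible rather
than cohort-calibrated (systolic jet recirculation of a few hundred mm/s;
diastolic regurgitant velocities of tens of mm/s distributed over the
lumen). Two numerical considerations fixed them:

* the ring amplitude is large enough that the retrograde annulus is a
  geometrically stable region at least ~2.7 mm wide at every active frame
  (full-ring reversal except near peak systole). A marginal ring (reversal
  confined to a sub-voxel rim) makes the
  reverse-flow integral ill-conditioned at 1 mm resolution — the lattice sum
  can deviate from the continuum integral by 10–20%;
* both reverse windows stay more than one frame away from the analytic
  end-systole frame, so the ±1-frame detection tolerance cannot move reverse
  volume between the systolic and diastolic windows.

For a raised-cosine ejection the inflection of the mean net-flow curve falls
at $3T_{es}/4$ — before flow actually stops; the ground-truth end-systole
frame is therefore defined by applying the same discrete rule to the analytic
noise-free curve, and the detector is validated against that frame.

## What the phantom does and does not show

The phantom exercises the complete pipeline — geometry, projection, phase
windowing, integration, artifact correction — against closed-form truth. It
is not a fluid-dynamics simulation: there is no jet eccentricity or helix, no
turbulence, no wall motion (the method itself assumes a static mask), no
respiratory motion and no k-space/coil physics. Passing its tests
demonstrates that the *measurement machinery* is unbiased to within a few
percent under the stated conditions, not that any physiological effect size
will be reproduced in patients.

Known quantitative behaviours, measured by the test suite:

* recovered segment means agree with the continuum ground truth to ≤ ~3%
  (noise-free) on the study phantom; tolerances of 5% (straight segments),
  10% (arch) and 15% (with 10 mm/s noise) are asserted;
* the recovered centerline length is within 2% of the analytic arc length;
  small systematic losses come from seed-voxel quantization and smoothing
  shrinkage of the arch;
* velocity fields are masked *before* interpolation (matching the intended
  acquisition workflow), so on coarse source grids trilinear blending with
  the zero background attenuates near-wall velocities; with 2 mm source
  slices the diastolic plug mean is recovered only to within ~25–40%. At the
  native 1 mm conditions this term vanishes;
* with velocity noise, rectified projection ($\max(0,-s)$) acquires a small
  positive bias at voxels whose true along-track velocity is near zero
  (≈ $\sigma/\sqrt{2\pi}$ per affected frame). Under the study conditions
  this contributes well under 5% of the systolic reverse-flow signal.

## Numerical choices

* **Frame indexing** is 1-based throughout the R API; the end-systole index
  `k_es` is the first diastolic frame, so systole = frames `1:(k_es - 1)` —
  a half-open split that makes whole = systole + diastole an exact identity.
* **Ties**: peak systole takes the earliest maximum; nearest-plane
  assignment takes the lowest plane index on exact ties.
* **Fallback**: if the second difference never turns non-negative after the
  peak (monotone concave decay), the post-peak minimum frame is used and a
  warning logged.
* **Distance transform**: iterative 6-connected erosion (city-block
  distance), box-blurred (3³, two passes) to remove integer plateaus, feeds
  the shortest-path weight $\ell / (d + 0.5)^3$. The cubed weight holds the
  path on the axis through the arch; the exponent trades corner-cutting
  against noise sensitivity and was fixed by the arch-tracking requirement.
* **Degenerate inputs**: empty static masks skip the offset correction with
  a warning; rank-deficient first-order fits fall back to order 0; seeds
  outside the mask, disconnected lumens, landmarks outside the centerline
  range and peak flow at the final frame raise errors rather than guessing.
* **Bland–Altman** reports LOA as the half-width $1.96\,\mathrm{SD}(d)$ and
  CoV as $100\,\mathrm{SD}(d)$ over the grand mean of all measurements; both
  conventions are stated in the output metadata.
* **ROI total**: the continuous circle area $\pi(d/2)^2$ (not an integer
  voxel count) multiplies the mean per-voxel reverse flow; totals are
  conventionally reported to 0.1 mL, while the function returns the exact
  value so linearity is preserved.

## Problem sizes used in validation

The bundled tests run the full study phantom (64 × 64 × 96 × 15, with and
without noise) once each for the recovery criteria, and smaller canes
(~40 × 28 × 56 × 12) for property and dissociation tests; the oracle
equivalence check uses random 16³ × 8 fields against a literal per-voxel
reference. These sizes were chosen so the whole suite completes in a couple
of minutes while every claim is still exercised at the study conditions.

## Limitations

* The centerline algorithm is one reasonable instantiation (distance-weighted
  shortest path); the method's contract is only the 1 mm plane spacing and
  tangent-normal geometry, not a specific extraction algorithm.
* Landmarks are supplied as arc-length positions in configuration; there is
  no interactive picker and no automatic landmark detection.
* Temporal unwrapping trusts the first frame and reports (rather than fixes)
  voxels needing more than one wrap per step.
* The segmentation is static in time; moving-wall analysis is out of scope.
* Sagittal MIP maps average over mask voxels only; background has no defined
  flow value.
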