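# revflow

Voxel-wise mapping of retrograde (reverse) blood flow in the thoracic aorta
from 4D flow cardiovascular MRI.

Aortic valve disease reshapes where and when blood flows backwards in the
aorta: valve stenosis throws an eccentric systolic jet whose counterpart is
near-wall flow reversal in the ascending aorta, while valve regurgitation
drains blood backwards through the valve in diastole along the whole vessel.
Conventional 2D plane-based measurements compress all of this into one
number at one location. `revflow` instead quantifies reverse flow at **every
voxel** of the segmented aorta and maps it by cardiac phase and anatomical
segment, for researchers working with time-resolved, three-directionally
velocity-encoded MRI of the thoracic aorta.

## The measurement

Given a velocity field $v_i(t)$ on a 1 mm isotropic grid, an aortic
segmentation and a centerline with orthogonal analysis planes every 1 mm,
each voxel is assigned to its nearest plane and its velocity projected onto
the plane's unit normal $\hat n$ (oriented away from the valve):

$$s_i(t) = v_i(t)\cdot\hat n, \qquad
  R_W = \sum_{t\in W}\max(0,\,-s_i(t))\;a\,\Delta t$$

with $a = 1\ \mathrm{mm}^2$ the voxel face area and $\Delta t$ the temporal
resolution. $R_W$ is the reverse-flow volume (mL) carried by that voxel over
window $W$: systole (frames before end systole), diastole, or the whole
included cycle. End systole is the first inflection of the whole-aorta mean
net-flow curve after peak systole; only frames inside the common 600 ms
window are used. Segment means over the ascending aorta (AAo), arch and
descending aorta (DAo), sagittal mean-intensity-projection maps, a
clinical-context ROI total $\pi(d/2)^2\,\bar R$, and Bland–Altman agreement
statistics complete the toolbox.

The package also ships a synthetic "candy-cane" aorta phantom
(`phantom_spec()` / `generate_phantom()`) with analytic ground truth —
including stenosis-like systolic ring reversal, regurgitation-like diastolic
plug reversal, eddy-current phase offsets, velocity noise and venc wrapping —
on which the entire pipeline is validated end to end.

## Worked example

Generate a diseased phantom (ring reversal 500 mm/s in systole, regurgitant
plug 60 mm/s in diastole, 10 mm/s velocity noise), run the full pipeline and
report per-segment reverse flow:

```r
library(revflow)

spec <- phantom_spec(
  reverse_ring = list(inner_fraction = 0.6, amplitude_mms = 500,
                      frame_range = c(3, 6)),
  regurgitant  = list(amplitude_mms = 60, frame_range = c(10, 15)),
  noise_sigma_mms = 10, seed = 42)

ds    <- generate_phantom(spec)
seeds <- phantom_seeds(ds)
run   <- reverse_flow_run(ds, seeds$valve, seeds$distal,
                          phantom_landmarks(spec))
run
#> <revflow_run> 38902 voxels, 139 planes; end systole at frame 9 of 15
#>  segment direction    window    mean_mL        sd_mL n_voxels
#>      AAo   reverse  systolic 0.02719130 0.0263778117     7664
#>      AAo   reverse diastolic 0.01440041 0.0009798794     7664
#>      AAo   reverse     whole 0.04159171 0.0264108753     7664
#>     Arch   reverse  systolic 0.02651685 0.0259444805    13626
#>     Arch   reverse diastolic 0.01415570 0.0010225153    13626
#>     Arch   reverse     whole 0.04067255 0.0259818556    13626
#>      DAo   reverse  systolic 0.02700956 0.0262545290    11264
#>      DAo   reverse diastolic 0.01440252 0.0009771077    11264
#>      DAo   reverse     whole 0.04141208 0.0262807729    11264
```

Each `mean_mL` is the average reverse-flow volume carried by a single 1 mm³
voxel over that window — deliberately small numbers. The analytic ground
truth for this phantom is 0.0264 mL (systole, all segments) and 0.0144 mL
(diastole); the pipeline recovers them within a few percent despite the
injected noise. To put the per-voxel scale in clinical context, assume every
voxel of a mid-ascending cross-section of diameter 42.8 mm experienced the
measured AAo systolic mean:

```r
m <- subset(run$segment_stats, segment == "AAo" & window == "systolic" &
                               direction == "reverse")$mean_mL
round(estimate_plane_total(m, 42.8), 1)
#> [1] 39.1
```

i.e. an estimated 39.1 mL of systolic reverse flow through that plane.
`export_results(run, "out/")` writes the maps (NIfTI), segment statistics and
centerline (CSV), MIP images (PNG) and a JSON manifest. A thin command-line
wrapper for generate/preprocess/compute/agree lives in `inst/cli/revflow.R`.

## Documentation

The methods vignette (`vignettes/reverse-flow-mapping.Rmd`) documents the
model and its assumptions, every tunable parameter with units and defaults,
what the phantom does and does not emulate, numerical choices (tie-breaking,
fallbacks, degenerate inputs) and known limitations.
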