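# muellerpli

Analysis tools for **multi-wavelength backscattering Mueller-matrix
polarimetry** of fibrous, birefringent samples — polymer fiber phantoms and,
by analogy, myelinated white matter. The package is aimed at researchers who
have per-pixel sample Mueller matrices (one 4×4 real matrix per pixel per
imaging wavelength) and want calibrated maps of polarization properties,
corrected for the retardance phase-wrapping artifact, together with the ROI
analyses used to study fiber geometry: crossing, inclination, out-of-plane
curvature, in-plane curvature and stage rotation.

## What it computes

Each pixel matrix is factored by the **Lu–Chipman polar decomposition**
`M = M_Δ · M_R · M_D` into depolarizer, retarder and diattenuator, giving
per-wavelength maps of

- retardance `R = acos(tr(M_R)/2 − 1)` (radians, in `[0, π]`),
- retardance angle (fast-axis orientation, degrees on `[0, 180)`),
- diattenuation `D = √(m01² + m02² + m03²)/m00` and its axis,
- depolarization power `Δ = 1 − |tr(M_Δ) − 1|/3`.

The inverse cosine folds true retardance above π back into `[0, π]` and
flips the recovered axis by 90° (**phase wrapping**); the package detects
the 90° axis discontinuities, corrects the mirrored retardance
(`2π − R`, or sign annotation for the around-zero branch), shifts the
affected angles by 90°, and chooses the mirroring branch by the
expected decrease of retardance with imaging wavelength.

The physics side is the **tilted uniaxial-crystal model**: a fiber inclined
out of plane by `θᵢ` shows retardance
`δ = (2πL/λ)·|nO·nE/√(nE²sin²θᵢ + nO²cos²θᵢ) − nO|`, strictly decreasing
from the in-plane value to 0 at 90°. A synthetic phantom generator renders
crossing / inclined / cylinder-wrapped / looping / rotated fiber scenes to
Mueller stacks with full per-pixel ground truth, so every analysis stage is
testable against known truth. Radius of curvature of surface cross-sections
is estimated with the SVD-based **Taubin circle fit**.

## Worked example

Simulate an inclined-fiber series, decompose it, and compare the recovered
ROI-mean retardance against the forward model:

```r
library(muellerpli)

med <- default_medium()   # nO = 1.59, nE = 1.57 (Δn = −0.02), L = 10 µm
scenes <- preset_phantom("inclined_series",
                         list(size = 32, inclinations = c(0, 20, 40, 60, 80),
                              n_fibers = 1, wavelengths = c(442, 532)))
for (i in seq_along(scenes)) {
  r    <- scene_to_mueller(scenes[[i]])
  maps <- decompose_stack(r$stack)
  fib  <- r$truth$fiber_id > 0
  incl <- attr(scenes, "series_values")[i]
  cat(sprintf("inclination %2d deg | recovered: %.4f rad (442 nm), %.4f rad (532 nm) | model: %.4f, %.4f\n",
      incl, mean(maps[[1]]$retardance[fib]), mean(maps[[2]]$retardance[fib]),
      tilted_retardance(med, incl, 442), tilted_retardance(med, incl, 532)))
}
```

```
inclination  0 deg | recovered: 2.8431 rad (442 nm), 2.3621 rad (532 nm) | model: 2.8431, 2.3621
inclination 20 deg | recovered: 2.5160 rad (442 nm), 2.0904 rad (532 nm) | model: 2.5160, 2.0904
inclination 40 deg | recovered: 1.6814 rad (442 nm), 1.3970 rad (532 nm) | model: 1.6814, 1.3970
inclination 60 deg | recovered: 0.7209 rad (442 nm), 0.5990 rad (532 nm) | model: 0.7209, 0.5990
inclination 80 deg | recovered: 0.0873 rad (442 nm), 0.0726 rad (532 nm) | model: 0.0873, 0.0726
```

Recovered means match the tilt model to numerical precision, decrease with
inclination, and are smaller at the longer wavelength — the three behaviors
the decomposition chain must preserve.

Crossing fibers, resolved-fiber ("top") overlap:

```r
r <- scene_to_mueller(preset_phantom("crossing", list(size = 32, wavelengths = 532)))
m <- decompose_stack(r$stack)[[1]]
h_top  <- angular_distribution(m$retardance_angle, r$truth$fiber_id == 2 & !r$truth$overlap)
h_over <- angular_distribution(m$retardance_angle, r$truth$overlap)
cat(sprintf("dominant angle, top fiber ROI: %.1f deg | crossing ROI: %.1f deg\n",
            h_top$dominant_angle, h_over$dominant_angle))
```

```
dominant angle, top fiber ROI: 117.5 deg | crossing ROI: 117.5 deg
```

The crossing region reads out the *top* fiber's orientation (fiber direction
30°, negatively birefringent, so the retardance axis sits 90° away at 120°;
the 5°-bin histogram reports the 117.5° bin center).

A config-driven end-to-end run (simulate → decompose → smooth → unwrap →
analyze → export) is available as `run_pipeline()` or from a shell via
`Rscript inst/cli/pli-pipeline.R config.yaml`.

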