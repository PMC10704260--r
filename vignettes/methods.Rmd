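---
title: "Methods: Mueller-matrix decomposition, phase unwrapping and fiber phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mueller-matrix decomposition, phase unwrapping and fiber phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerpli)
```

## Scope and model

`muellerpli` analyses per-pixel Mueller-matrix image stacks of the kind
produced by multi-wavelength backscattering polarized light imaging (PLI) of
anisotropic fibrous samples — birefringent polymer fiber phantoms and, by
analogy, myelinated white matter. The package covers the analysis side only:
its inputs are calibrated sample Mueller matrices (one 4×4 real matrix per
pixel per wavelength). Instrument-side reconstruction (Stokes decoding,
calibration) is out of scope, as are coherent (Jones) superposition, Monte
Carlo light transport and feature-based image registration.

A fiber is modeled as a uniaxial medium with ordinary index $n_O$,
extraordinary index $n_E$ and effective path length $L$. Light traversing it
acquires a retardance

$$\delta = \frac{2\pi\,\Delta n\, L}{\lambda}, \qquad \Delta n = n_E - n_O,$$

and tilting the optic axis out of the imaging plane by the inclination
$\theta_i$ replaces $n_E$ with the effective index

$$n_e(\theta_i) = \frac{n_O n_E}
{\sqrt{n_E^2 \sin^2\theta_i + n_O^2\cos^2\theta_i}},$$

so that the measured (magnitude-only) retardance is

$$\delta(\theta_i,\lambda) = \frac{2\pi L}{\lambda}\,
\bigl|\,n_e(\theta_i) - n_O\,\bigr|.$$

Two published forms of the effective-index denominator disagree (one writes
$\cos^2(\pi/2-\theta_i)$, the other $\cos^2\theta_i$); the package adopts the
$\cos^2\theta_i$ form, which is the one consistent with the physics it is
meant to express: $\delta$ decreases strictly with inclination and vanishes
at $\theta_i = 90^\circ$, and the five per-wavelength curves never cross.
$L$ is treated as independent of inclination and wavelength; in a real
backscattering geometry $L$ follows the photon mean free path and is
wavelength dependent, which is a known limitation of this model, not of the
implementation.

Negative birefringence ($n_E < n_O$, the white-matter and polystyrene case)
enters twice: the magnitude $|\Delta n|$ in $\delta$, and the orientation
convention — for a negatively birefringent fiber the recovered retardance
axis is *perpendicular* to the fiber tangent, for a positively birefringent
one it is parallel.

## Conventions

All orientations are axial quantities: degrees on $[0, 180)$, $0^\circ$
horizontal pointing right, counterclockwise positive (`mueller_convention()`
returns the canonical string, which every container and sidecar carries).
The reported retardance axis is the **fast** axis; whether a given
instrument reports fast or slow axis is generally undocumented, so the
convention is fixed and exposed rather than guessed. Axial statistics
(means, smoothing, interpolation) are computed in doubled-angle space
$(\cos 2\theta, \sin 2\theta)$ throughout.

## Lu–Chipman decomposition

Each pixel matrix is factored as $M = M_\Delta M_R M_D$ (depolarizer ·
retarder · diattenuator, the classical factor order). The diattenuator is
built analytically from the first row; the depolarizer block is the
symmetric polar factor of $m' = m_\Delta m_R$, obtained from the eigenvalues
of $m'm'^T$ with the sign of $\det m'$; the retarder is $m_R =
m_\Delta^{-1} m'$. Scalar summaries are the standard ones:

* retardance $R = \cos^{-1}\!\left[\operatorname{tr}(M_R)/2 - 1\right] \in [0,\pi]$,
* diattenuation $D = \sqrt{m_{01}^2+m_{02}^2+m_{03}^2}/m_{00} \in [0,1]$,
* depolarization power $\Delta = 1 - |\operatorname{tr}(M_\Delta)-1|/3 \in [0,1]$
  (the depolarization metric is not uniquely fixed by vendor map software;
  the standard Lu–Chipman power is adopted and documented).

Numerical choices: eigenvalues of $m'm'^T$ are clamped at $10^{-12}$ and the
pixel flagged `degenerate` rather than failing, so maps stay rectangular;
pixels whose matrices cannot be decomposed (non-finite, $m_{00}\le 0$,
$D \ge 1$, reconstruction residual above $10^{-6}$) are marked invalid and
counted, never silently filled. Axes are reported `NA` when $R$ or $D$ falls
below $10^{-6}$ — an arctangent of noise would otherwise pollute angular
histograms. At an exact half-wave retardance ($R = \pi$) the axis is
intrinsically ambiguous modulo $90^\circ$; the fallback readout documents
this.

## Phase wrapping and its correction

Because $R$ comes from an inverse cosine, true retardance above $\pi$ is
mirrored back into $[0,\pi]$ and the recovered axis flips by exactly
$90^\circ$ — an identity of the retarder algebra
($M(\delta,\theta) = M(2\pi-\delta,\,\theta+90^\circ)$), not a numerical
artifact. The correction pipeline is:

1. `detect_wrapped_regions()` scans an angle profile (or map, row by row)
   for axial jumps of $90^\circ \pm 20^\circ$ (both defaults configurable)
   and flags the region beyond each jump, toggling at every further jump.
   Samples exactly at a discontinuity are assigned to the flagged side
   (an arbitrary but fixed choice).
2. `apply_unwrap()` corrects flagged entries: $R' = 2\pi - R$ if the data
   were mirrored around $\pi$, or a sign annotation with preserved magnitude
   if mirrored around zero (downstream maps are magnitude-based); the angle
   shifts by $+90^\circ$. Unflagged entries pass through bit-identical, and
   corrected outputs carry a flag so that double correction is refused.
3. `select_branch()` makes the branch choice algorithmic instead of
   subjective: mean ROI retardance is expected to decrease with imaging
   wavelength, so the branch with the fewest monotonicity violations wins;
   ties select the around-$\pi$ branch with an ambiguity flag, and if no
   candidate is monotone no choice is made silently.

A 1-D scan cannot know which *side* of a jump is the wrapped one (a profile
may begin inside the wrapped region), so the pipeline orchestrator also
evaluates the complement of the detected mask as a candidate, under both
branches, and lets the same wavelength-monotonicity rule arbitrate among the
four combinations. Full 2-D unwrapping algorithms (Goldstein,
quality-guided) are deliberately out of scope: the correction here is
mask-based.

## ROI analyses

* **Smoothing** (`smooth_maps`, default $\sigma = 10$ px): normalized masked
  Gaussian convolution — invalid pixels contribute nothing and the kernel is
  renormalized over the valid support. Angle maps are smoothed in
  doubled-angle space. Note that border/mask renormalization is asymmetric,
  so the global mean is preserved exactly only where no kernel mass is lost
  (the property tests assert total conservation for interior-supported
  maps); constant maps are always preserved.
* **Angular histograms** (`angular_distribution`, default 36 bins of
  $5^\circ$, matching the granularity of typical radial plots): normalized
  to unit maximum; the dominant angle is the modal bin center, with ties
  resolved by the circular mean of tied centers. The readout therefore
  carries a half-bin quantization; analyses that compare a dominant angle
  against an exact orientation should choose a bin width placing that
  orientation at a bin center (the acceptance script uses $4^\circ$ bins for
  this reason). Weighting (e.g. by retardance) is exposed as an option; ROI
  angle means default to the unweighted circular mean.
* **Path profiles** (`profile_along_path`): stations at 1-px arc-length
  spacing along a polyline; at each station valid pixels within half the
  transverse width of the local normal are averaged. The transverse width
  has no canonical value and defaults to the caller's choice (the fiber mask
  extent when ground truth is available). `linear_fit_profile` reports the
  OLS slope (units per µm), intercept and $R^2$.
* **Rotation series** (`register_rotation`, `rotation_series_analysis`):
  registration is by the *known* stage angle (bilinear inverse mapping;
  angle values additionally shift by $-\text{stage}$), never by feature
  matching. Retardance means are fit to the $180^\circ$-periodic sinusoid
  $a\cos(2(\varphi-\varphi_0)) + c$ (the axial symmetry fixes the period;
  at least 4 orientations required), angle means to a line after axial
  unwrapping, with unit slope expected when the recovered axis tracks the
  stage.

## Taubin circle fit

Radius of curvature from 2-D cross-section points uses Taubin's algebraic
circle fit in its SVD form: centroid-center the points, scale
$z = x^2+y^2$ by $2\sqrt{\bar z}$, and take the smallest right singular
vector of $[\,(z-\bar z)/2\sqrt{\bar z},\; x,\; y\,]$. Collinear input
(vanishing quadratic coefficient) raises a degenerate-geometry error rather
than returning an enormous radius. Point extraction from images is upstream
of this module; it consumes plain point sets.

## The synthetic phantom generator

`preset_phantom()` builds the five study geometries — crossing fibers,
inclined series, cylinder wrap (out-of-plane curvature), in-plane loop, and
rotation series — as scenes of dilated-centerline fibers over a pure
depolarizer background (a dark foil has no anisotropy; default
$a=b=c=0.2$). Per fiber pixel the matrix is
$M_{\text{bg}} \cdot M_R(\delta(\theta_i,\lambda), \text{axis})$, optionally
followed by a linear diattenuator; the axis is the local tangent
($+90^\circ$ for negative birefringence). Defaults, chosen once as the
study conditions:

| parameter | default | rationale |
|---|---|---|
| wavelengths | 405, 442, 473, 532, 632 nm | the instrument's five-wavelength set |
| pixel pitch | 10 µm | the instrument's resolution scale |
| image size | 64 px | desk-scale scenes; tests use 24–48 px |
| fiber diameter | 60 µm | synthetic-hair scale (6 px footprint) |
| medium | $n_O{=}1.59$, $n_E{=}1.57$, $L{=}10$ µm | polystyrene-like, $\Delta n=-0.02$; $\delta(532){\approx}2.36$ rad, inside $[0,\pi)$ at all five wavelengths when untilted |
| background | diag(1, 0.2, 0.2, 0.2) | strongly depolarizing dark background |
| noise | 0 (off); tests use $\sigma{=}0.02$ | element-space Gaussian, scaled by m00 |

Where two fibers overlap, `top` mode copies the top fiber's matrices
bit-for-bit (resolved-fiber behavior) and `average` mode takes the
element-wise mean of the single-fiber matrices (unresolved bulk-tissue
behavior). The physical mechanism behind which regime applies in real data
(resolution vs depth) is an open experimental question, so both modes are
exposed rather than decided. Incoherent element-wise averaging is itself a
modeling choice; the averaging observation in tissue does not state a
mechanism. One consequence worth knowing: the midpoint-orientation reading
of the averaged composite is a *small-retardance* phenomenon. For two
strong retarders ($\delta$ approaching $\pi$) the element-wise mean
degenerates toward a half-wave retarder whose axis readout is ambiguous
modulo $90^\circ$; the averaging-mode tests therefore run at tissue-scale
retardance ($L = 4$ µm, $\delta(532) \approx 0.94$ rad), the regime the
mode emulates.

Noise is applied in Mueller-element space (i.i.d. Gaussian per element,
scaled by the pixel's m00, deterministic under the recorded seed), with
per-wavelength sigmas so that noise can grow with wavelength as observed in
phantom data. Matrices pushed past the passivity bound $|m_{ij}| \le m_{00}$
are flagged in metadata, never repaired; the decomposition independently
invalidates pixels it cannot factor, and the per-wavelength failure count is
part of every pipeline log.

What the generator does **not** emulate: speckle, Savart-plate
interferograms, volumetric light transport, depth-dependent path length,
polymer dispersion beyond an optional per-wavelength birefringence table,
and tissue heterogeneity. Passing tests therefore demonstrate the
correctness of the analysis chain on data that obey the forward model
exactly (plus element-space noise) — they bound implementation error, not
model error on real tissue.

## Containers and determinism

Stacks are stored as multi-page 32-bit float TIFFs (16 planes per
wavelength, m00…m33) with a JSON sidecar recording wavelengths, pixel
pitch, the angle convention string, the corrected flag, the seed, and the
affine map used to place values in the TIFF writer's [0,1] float domain
(NA entries use an out-of-band sentinel). Round trips are exact at float32
precision. Every pipeline artifact carries enough metadata to re-derive it,
and re-running `run_pipeline()` from the same config and seed reproduces
`summary.tsv` byte-identically.

## Problem sizes

The test suite and acceptance script run entirely on synthetic scenes:
24–48 px images, 1–5 wavelengths, 100-station ramps, 1000 random
decomposition triples, 100-seed circle-fit and 20-seed crossing suites —
sizes chosen so the whole suite completes in well under a minute of
per-module time while still exercising every geometry at all five
wavelengths.
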