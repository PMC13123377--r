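---
title: "Methods: traction force microscopy and implantation biomechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traction force microscopy and implantation biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryotfm)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they rest on, the parameters that matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices a maintainer would
want written down.

## The measurement problem

An implanting embryo adheres to a soft gel and pulls on its surface.
The observable is the motion of fluorescent beads embedded in a thin
layer at the gel surface, imaged under load and again after the embryo
has been removed (the relaxed reference). The pipeline recovers, in
order: rigid stage drift (instrumental, removed), the gel surface
displacement field (μm), the traction stress field (Pa), and per-frame
force metrics whose time series carry the biology — ramping during
adhesion, bounded fluctuation with roughly 10-minute peak recurrence,
and rapid decline under cytoskeletal inhibition.

## Elastic model and its assumptions

The substrate is modelled as a homogeneous, isotropic, linear-elastic
**half-space**. The real gels are ~150 μm thick; the half-space
approximation is standard FTTC practice and is justified here because
thickness exceeds both the bead displacements (≤ a few μm) and the
lateral decay length of the load. Finite-thickness kernels are a known
refinement and deliberately out of scope. Poisson's ratio defaults to
0.5 (incompressible, the convention for hydrated gels); Young's modulus
is the measured substrate stiffness (1–10 kPa in the regime of
interest). Tractions are tangential and two-dimensional: out-of-plane
components and 3-D bead motion are not modelled — a stated limitation of
projection-based TFM generally.

The forward map is the Fourier-space Boussinesq tensor (see the README
for the expression); the package's `forward_displacement()` agrees with
the closed-form single-mode kernel to < 1e-10 relative error, which is
the anchor for everything downstream.

## Numerical choices in the inversion

- **Zero-padding factor 2 per axis** before FFTs, with a raised-cosine
  taper (default 10% of each margin) on the displacement field in the
  inverse. The discrete transform imposes periodicity; padding plus
  tapering suppress wrap-around leakage. On a centred embryo-scale
  scene (annulus outer radius 55 μm in a 512 μm field) the noise-free
  round trip then recovers the traction to ~2% relative L2 error; the
  residual is the information genuinely lost outside the field of view.
- **k = 0 mode set to zero** in both directions: the rigid translation
  of a half-space under net load is undefined, and zeroing it enforces
  a force-balanced reconstruction.
- **Regularization**: Tikhonov per mode, `T̃ = (G̃ᴴG̃ + λ²I)⁻¹G̃ᴴũ`, with a
  Wiener-style variant in which λ² scales with the per-mode kernel norm.
  λ defaults to the **noise-matched** (discrepancy-principle) choice:
  the value at which the forward-model residual (measured over the
  untapered interior, and log-interpolated between sweep candidates)
  reaches τ times the displacement noise of an embryo-free region. The
  node-level noise is estimated as the robust spread of the residual
  from a 3×3 local median — raw RMS would include the real (smooth)
  far-field displacement and over-smooth. That estimator is blind to
  the spatially *correlated* part of the PIV error, which shares the
  bandwidth of the interrogation windows; the safety factor τ (default
  4) compensates and was calibrated on synthetic scenes against known
  ground truth — the simulator makes that calibration reproducible,
  and τ is exposed in the configuration. L-curve-corner and fixed-λ
  strategies are available; the chosen strategy and value are logged
  and stamped into the per-frame metrics.
- **Units**: the conversion 1 Pa·μm² = 10⁻³ nN is hard-coded and
  unit-tested; silent unit errors are the classic failure mode of TFM
  code.

## Drift registration

Stage drift is a rigid translation; gel deformation is signal. Drift is
estimated by full-frame cross-correlation (optionally restricted to a
user template region, reproducing the template-matching workflow) with
3-point parabolic subpixel refinement, relative to a reference frame
(default: the first). Frames whose normalized correlation falls below
0.2 are flagged and their shifts interpolated from neighbours.
Compensation resamples by the negated shift with bilinear interpolation
(bicubic by flag). On rendered bead images integer drifts are recovered
exactly and subpixel drifts to well under 0.1 px.

## Displacement estimation (PIV)

Displacements are measured by window cross-correlation: 32-px windows at
50% overlap (common PIV defaults), Gaussian 3-point subpixel peak fit,
correlation normalized by the window overlap area at each lag (the
"unbiased" estimator — without it, loss of bead pairs biases every
estimate toward zero by a factor ≈ 1 − d/N). Estimation is **multipass
with image deformation** (default 3 passes): after each pass the loaded
image is warped back by the current field estimate and the residual is
re-measured. This suppresses the window-averaging bias where the
displacement gradient is steep (the annular traction rim) and is what
brings field recovery to ~8% RMS of the true field RMS on default
scenes. Windows without bead texture, or with peak correlation below
0.2, are masked invalid. Outliers are screened by a local median/MAD
test with a measurement-noise floor of 0.05 μm (the normalized-median
convention of ~0.1 px at 0.5 μm/px) and replaced by the local median,
with counts logged.

The sign convention is fixed and tested: displacement is
loaded-relative-to-relaxed, so the reconstructed traction is what the
embryo exerts on the gel. Coordinates are 0-based pixel centres, x
right, y down, converted to μm by the pixel size.

The MSD exponent in `migration_stats()` is fitted over the first 10 lags
only, although the MSD curve itself is reported out to a quarter of the
track span: time-averaged MSD values at long lags share few independent
increments and wander coherently, and an exponent regressed over the
full quarter-span range misses the diffusive value by more than 0.1 for
roughly a third of random seeds at 1000 steps, while the short-lag fit
is unbiased with SD ≈ 0.03. This is the standard compromise in
migration analysis.

## What the simulator emulates — and what it does not

`simulate_scene()` + `render_bead_images()` produce: a single plane of
beads at uniform random positions, rendered as isotropic Gaussian spots
(σ = 1.5 px) on a constant background; displacement of each bead by the
forward-model field; rigid per-frame drift; optional Poisson counting
noise on 16-bit intensities. Defaults: 0.5 μm/px, spot amplitude 8000
counts on background 400, bead density 0.015 px⁻² — about 15 beads per
32-px interrogation window, following the standard PIV seeding guidance
of at least ~10 particles per window. Density, spot size and noise are
configurable and recorded in the scene's JSON sidecar, since the
source imaging protocol does not pin them down.

The contractile truth is an inward radial annulus with a smooth sin²
radial profile; discrete sampling residuals of the net force are removed
by a magnitude-weighted correction confined to the annulus, so every
scene is self-balanced to numerical tolerance. Auxiliary generators
produce Hertz force–indentation curves, periodic peak trains (ramp +
jittered Gaussian bumps), persistent-random-walk trajectories, and
two-channel YAP/nucleus images with analytically known ratios.

Not emulated: 3-D bead stacks, viscoelastic or nonlinear gel rheology,
photobleaching, bead aggregation or polydispersity, optical aberrations,
non-rigid stage wobble, and any embryo mechanosensing feedback. Passing
recovery tests on these scenes therefore demonstrates correctness of the
measurement chain under its own model assumptions — not robustness to
every pathology of real microscopy data.

## The stiffness → max-traction direction

Observed biology shows lower max traction on stiffer substrates. In
simulation we hold the embryo's force program fixed and run the *same*
scene at E = 1, 4, 10 kPa through the full chain. Recovered max traction
then falls monotonically with stiffness — not because the simulated
embryo adapts, but because the displacement signal scales as 1/E while
the measurement noise does not, and noise-matched regularization must
suppress relatively more of the band. The package reproduces the
direction as a property of the measurement chain under a fixed force
program; disentangling instrumental attenuation from genuine
mechanoresponse in real data would require stiffness-matched SNR, which
is worth keeping in mind when comparing absolute traction values across
stiffness groups.

## Hertz indentation fitting

Model: F = (4/3)·E/(1−ν²)·√R·max(δ−δ₀, 0)^{3/2}, with the tip radius
R = 3 μm of the nanoindenter probes and ν = 0.5. E enters linearly once
the contact offset δ₀ is fixed, so the joint fit is a 1-D search over δ₀
with the closed-form least-squares E inside — robust on soft gels where
contact is gradual. A threshold-based contact pre-detector (first force
above 3 baseline SD) is available for comparison with vendor software.
When a sample thickness is supplied, fitting is restricted to
indentations below 10% of it (thin-sample validity). QC flags replicate
the practice of excluding irregular curves: adhesion excursions below
baseline, non-monotone post-contact force, baseline drift, and
non-contact. The drift band uses the SD of the *detrended* baseline —
a band computed from the raw baseline would be inflated by the very
drift it is meant to detect. Point summaries average E over passing
fits only and report exclusion counts.

## Morphometry definitions

- **Circularity** 4πA/P², with area from the pixel count and perimeter
  as the 0.5-level contour length of the mask after a σ = 2 px Gaussian
  smoothing — chain-code perimeters overestimate smooth outlines by up
  to ~8%, which would bias circularity low; the smoothed-contour
  estimator is within 2% for both squares and large disks.
- **Core structure**: equivalent (area-matched) diameter strictly
  greater than 80 μm.
- **Interface metrics**: the EPI/pTE interface is the chain of midpoints
  between adjacent pixels of the two masks. Arc is the polyline length;
  chord the endpoint distance; **curvature** the angular extent (in
  degrees) of the points about a least-squares circle fit, which reads
  0° for straight interfaces and 180° for semicircles and remains valid
  past 180°. **Relative interface** is not operationally defined in the
  source imaging literature; here it is chord / EPI width (EPI extent
  along the chord direction), so a full-width interface scores 1 —
  consistent with the expectation that it approaches 1 as cup-shaped
  morphology develops. This definition is a documented package decision.
- **Adhesion onset**: two-segment piecewise-linear fit (common
  breakpoint, both series standardized, grid search over interior
  samples) to the area and circularity series against time; collinear
  data are flagged rather than assigned an arbitrary breakpoint.

## Dynamics parameters

Peak prominence defaults to 20% of the series interquartile range, and
the "significant displacement" threshold in peak→movement association to
twice the median per-interval step — both are explicit, configurable
defaults because the underlying phenomena (what counts as a peak, what
counts as movement) have no canonical scale. A 10-minute peak period
sampled at 5-minute frames sits at the Nyquist limit; `detect_peaks()`
and `validate_config()` warn whenever the mean interval is below three
sampling intervals, so interval statistics near that limit are not
over-read.

## Problem sizes

Validation scenes are 1024×1024 px (0.5 μm/px) with a 64-node traction
grid for full-chain checks, 128-node grids for dense round trips, 50
Monte-Carlo seeds for indentation noise studies, and 100-peak trains for
interval statistics — sizes at which every recovery quantity is stable
run-to-run under a fixed seed.

## Known limitations

2-D projection of a 3-D contact; half-space elasticity; translation-only
registration; window-resolution limits on sharp traction features (the
reconstructed maximum is a smoothed lower estimate of the true point
maximum — compare like with like across conditions); no automatic
cell/nucleus segmentation (masks are inputs); interval-based rather than
spectral periodicity analysis.
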