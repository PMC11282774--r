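---
title: "Quantifying cell mechanoporation: models, estimators and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell mechanoporation: models, estimators and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanopore)
```

## The experiment this package quantifies

In contactless viscoelastic mechanoporation, suspended cells flowing
through a microfluidic channel in a dilute polymer solution are
compressed by elastic normal stresses — no walls or constrictions touch
the cell. The compression force grows as
$F \propto \beta^3\,\eta\,\lambda\,U_{max}^2$ with the confinement ratio
$\beta$ (cell diameter over channel height), fluid viscosity $\eta$,
relaxation time $\lambda$ and peak flow velocity $U_{max}$. A spherical
cell ($a = c$) flattens into an oblate spheroid ($a = b > c$), the
membrane curvature steepens at the equator, membrane tension rises, and a
transient micrometre-scale pore opens there. The pore admits
nanoparticles by passive diffusion before the cortex and membrane reseal
over roughly ten minutes.

The package implements the downstream quantitative analyses as reusable,
tested functions, together with synthetic ground-truth generators for
every input modality, so that each estimator can be validated end to end
without any microscope data. Measurement conditions follow the
experimental design: `Ctrl` (never compressed), `Compressed` (in flow),
`T0` (~1 min after compression) and `T1` (~10 min after).

## Cell shape and curvature

A compressed cell is an oblate spheroid with equatorial semi-axes
$a = b$ and polar semi-axis $c \le a$, built from in-flow measured
diameters with `make_oblate(2a, 2c)`. With the squared first eccentricity
$e^2 = (a^2 - c^2)/a^2$ the principal radii along the meridian are

$$\rho_1(\varphi) = \frac{a\,(1 - e^2)}{(1 - e^2\sin^2\varphi)^{3/2}},
  \qquad
  \rho_2(\varphi) = \frac{a}{(1 - e^2\sin^2\varphi)^{1/2}},$$

where $\varphi$ is the geodetic latitude (0° at the equator, 90° at the
pole). Curvatures are $C_i = 1/\rho_i$ and the total curvature
$J = C_1 + C_2$ is maximal at the equator — the geometric argument for
equatorial pore formation. Two conventions in circulation deserve
comment, and both were decided by validation rather than taste:

* The quantity $(a^2-c^2)/a^2$ is sometimes written as the "first
  eccentricity" $e$ itself. Treating it as $e^2$ (the geodesy
  convention) is the only reading that reproduces the classical limits
  $\rho_1(0) = c^2/a$, $\rho_2(0) = a$ and $\rho_1 = \rho_2 = a$ for a
  sphere.
* The prime-vertical radius $\rho_2$ occasionally circulates with the
  exponent $3/2$ instead of $1/2$. The default (`variant = "classical"`)
  uses $1/2$; the test suite checks both radii against an independent
  finite-difference differential-geometry oracle on the meridian ellipse
  (relative error below $10^{-6}$ on a 91-point grid over 50 random
  shapes). The transcription with exponent $3/2$ is available as
  `variant = "exponent32"` for auditability; it fails the oracle away
  from the sphere limit and is not used anywhere.

For a control sphere the package reports both the single curvature $1/a$
and $J = 2/a$; summaries quote $1/a$ (≈ 0.12 µm⁻¹ for a 16.7 µm cell)
because that is the conventional single-number curvature of a sphere.
The compression-force scaling is exposed with proportionality constant 1,
so only ratios between parameter settings are meaningful.

## Fluorescence-lifetime fitting (membrane tension readout)

The tension probe's photon decay is biexponential,
$I_1 e^{-t/\tau_1} + I_2 e^{-t/\tau_2}$; the majority-signal lifetime
$\tau_1$ is the tension readout (~4.7 ns in quiescent cells, rising ~12%
just after compression, ~6.5 ns at high-tension spots).
`fit_biexponential()` uses bounded Levenberg–Marquardt least squares with
Poisson-motivated weights $1/(\text{counts}+1)$ and a multi-start grid of
log-spaced lifetime pairs; non-convergence is flagged, never silent.
Components are ordered by *signal share* $I\,\tau$, not by lifetime
magnitude, so $\tau_1$ is always the component carrying the majority of
photons. An optional constant-background term is available; instrument
response deconvolution is not modelled (the synthetic decays are
generated without an IRF), which is the main simplification relative to
hardware data. At $10^5$ photons the median relative error of
$\hat\tau_1$ over the design range ($\tau_1 \in [3, 7]$ ns, amplitude
ratios 4:1–19:1) is under 1%.

## High-tension point mapping and angular statistics

Lifetime colour maps render high tension in red. The analysis chain is:
Otsu threshold on the grayscale silhouette → largest connected region →
least-squares circle fit of its boundary (`segment_cell_circle()`) →
red-channel window [120, 180] (inclusive, 8-bit) with connected clusters
collapsed to centroids so one physical spot counts once
(`detect_high_tension_points()`) → normalized polar coordinates
(`polarize_points()`). The angular convention is mathematical
(counter-clockwise from +x, y up); image rows are flipped internally.
Points with normalized radius above 1.1 are flagged as outside the fitted
circle but kept — boundary pixels of a fitted circle legitimately land
just outside it.

`angular_concentration()` bins angles into the eight fixed sectors
[0°, 45°), …, [315°, 360°). Under a uniform distribution each bin expects
exactly 12.5% of points; the reported statistic is the largest bin's
share. The bin phase is fixed at 0° — a sector of planted points that
straddles a bin edge therefore yields at least 50% rather than 100%, and
a phase-scanning variant is available (`phase_scan = TRUE`) but is not
the default statistic. Rotation covariance (rotating the image rotates
every angle and changes nothing else) is exact and tested.

## Actin cortex morphometry

The cortex is measured as an annular region of interest: thickness is
defined as $(R_{major} - R_{minor})/2$ and the ring intensity is
normalized by the annulus area $\pi(R_{major}^2 - R_{minor}^2)$.
`estimate_cortex_ring()` recovers the radii from a radial intensity
profile (1-px shells about the centre, ring = contiguous span above half
the profile peak), which is robust for the ring-like images the cortex
channel produces. The synthetic study conditions place the thickness at
~0.7 µm (Ctrl), ~0.4 µm (T0) and recovered at T1.

## Nanoparticle counting in z-stacks

Counting follows volumetric thresholding: within an axial analysis slab,
voxels above a per-size threshold are counted, the occupied volume is
voxel count × voxel volume, and the particle count is occupied volume
divided by the nominal single-particle volume $(4/3)\pi(d/2)^3$ — real
valued, since aggregates are divided, not declumped. For 44 nm particles
only the voxel count is reported; the volume conversion is not meaningful
at that size. The slab excludes a depth of 10% of the cell's major radius
from the top and bottom of the stack, converted to whole slices by
ceiling (conservative exclusion).

Two numerical choices matter and are worth stating plainly:

* **Resampling before thresholding.** At the acquisition spacing
  (dz = 0.35 µm) a 200 nm particle is sub-slice: whether it falls inside
  one slice or straddles two changes its voxel footprint by a factor of
  about two, and thresholded volumes inherit that quantization. Stacks
  are therefore smoothed with a small matched filter (σ = 1 px lateral,
  1.2 slices axial by default) and resampled ×(2, 2, 4) by Fourier
  (sinc) interpolation before thresholding. Because a Gaussian-blurred
  acquisition is band-limited, the reconstruction is offset-invariant and
  the quantization largely disappears.
* **Reference-bead threshold calibration.** The threshold is the
  intensity at which an isolated reference bead's apparent
  (above-threshold) volume equals the nominal volume of one particle,
  pooled over a bead field imaged and pre-processed exactly like the
  stacks (`calibrate_np_threshold()`, `gen_np_reference()`). This is the
  only threshold definition under which occupied-volume division returns
  the true count for isolated particles: a mean-of-brightest-pixels rule
  (`np_threshold_brightest()`) sits near the blurred blob's peak and
  yields an apparent volume of nearly zero, so it is kept only for
  comparison. An explicit numeric override is accepted everywhere.

With this chain, planted counts on noisy synthetic stacks (Poisson mean
30, peak SNR 10) are recovered within ±10% in well over 90% of stacks for
200 and 500 nm particles. Delivery efficiency is the treated-to-control
ratio of counts (~12× at T0 and ~6× at T1 for 200 nm, ~3× for 500 nm at
T1 under the default study conditions); a zero control count returns an
explicit undefined marker. Colocalization converts colocalized voxels to
particles via the apparent voxels-per-particle and reports a percentage
of internalized particles, capped at 100 with a warning.

## Transport classification from tracking

Per track, the time-averaged MSD is computed over all frame pairs at each
lag, and $\log \mathrm{MSD}$ is regressed on $\log \tau$: the slope is
the anomalous exponent $\alpha$, and for diffusive tracks
$D = \text{prefactor}/4$ (2-D). Fits with $R^2 \le 0.75$ (strict) are
rejected; accepted tracks are diffusive when $\alpha \le 1$ and actively
transported when $1 < \alpha < 2$, with $\alpha \ge 2$ labelled
transported plus a ballistic-boundary warning.

The fitted lag range defaults to the first quarter of the trajectory
(`max_lag_fraction = 0.25`). Long lags of a time-averaged MSD have few
effective samples and inflate the variance of $\hat\alpha$ badly: with
the default acquisition (41 frames at 0.5 s), quarter-length fitting
keeps single-track Brownian $\hat\alpha$ within [0.6, 1.4] about 98% of
the time versus ~87% for half-length fitting.

One honest limitation must be understood when reading population
fractions. For a truly Brownian track, $\hat\alpha$ is (nearly) unbiased
around 1, so a *hard* cut at $\alpha \le 1$ classifies roughly half of
genuinely diffusive tracks as transported no matter how the fit is tuned
— the measured diffusive share systematically underestimates the true
one (a 60% diffusive mixture reads as ~35%). Directed tracks, by
contrast, separate cleanly ($\hat\alpha \approx 1.9$ with tiny spread).
The hard threshold is retained because it is the field's stated rule;
analyses that need calibrated fractions should either test
$\alpha$ against 1 with a confidence interval or compare conditions by
the *shift* in measured fractions, which is unaffected by the symmetric
boundary loss.

## Pore-diffusion simulator

The uptake simulation solves Fick's second law with spatially varying
diffusivity on an axisymmetric cylindrical finite-volume grid: a
spherical cell on the symmetry axis of a box of particle suspension,
initial concentration 1 outside the cell and 0 inside (the dosing
concentration acts only as a normalization). The membrane is not meshed
as a shell — resolving a 50 nm layer would force an impractical grid —
but enters as a series resistance $t_m / D_m$ on the finite-volume faces
crossing the sphere, exactly zero conductance when $D_m = 0$. A circular
pore centred on the +z pole removes the barrier locally; faces partially
inside the pore cone get fractionally weighted conductances, which makes
the uptake converge smoothly under grid refinement (halving the spacing
changes the 5-minute uptake by under 2%).

Time stepping is backward Euler with one sparse Cholesky factorization
reused for every step: unconditionally stable, and mass-conserving to
solver precision (relative drift ~10⁻¹³; the solver aborts if drift ever
exceeds 10⁻⁶). A uniform-diffusivity run reproduces the analytic 3-D heat
kernel to < 2% RMS.

Compartment transport parameters are not measured quantities and are
documented defaults: T = 310 K, bulk viscosity 0.7 mPa·s (water at
37 °C), cell interior 3× bulk, membrane impermeable outside the pore,
membrane thickness 50 nm; diffusivities follow Stokes–Einstein
$D = k_B T / (3\pi\mu d)$ (≈ 3.2 µm²/s for 200 nm particles in the
bulk). The two study configurations are a 1.5 µm pore probed over 5 min
and a 0.5 µm pore over 20 min; uptake is monotone in pore diameter and
in membrane permeability. The simulator reports normalized intracellular
amounts, not absolute particle counts; no advection, electrostatics or
particle–membrane interactions are modelled, and simulated uptake should
not be compared to absolute experimental counts without an explicit
dosing calibration.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its parameters and a seed.

* `gen_decay()` draws multinomial photon counts over time bins from the
  exact integral of the biexponential density — shot noise is modelled,
  IRF, afterpulsing and background are not.
* `gen_tension_image()` plants rim points at known angles on a silhouette
  whose red channel lies outside the detection window — real lifetime
  maps have graded colour and autofluorescence this does not imitate.
* `gen_zstack()` renders spheres through a Gaussian PSF *before* slice
  sampling (the physically correct order — sampling first aliases
  sub-slice structure irrecoverably), normalizes each bead's integrated
  intensity, and adds Gaussian camera noise scaled to the single-bead
  peak. Planted particles keep a PSF-aware minimum separation so ground
  truth corresponds to optically distinguishable puncta; heavily fused
  aggregates, uneven cellular background and bleaching are not emulated.
* `gen_trajectories()` mixes Brownian tracks (per-axis step variance
  $2D\,\Delta t$, verified to 5%) with directed tracks (constant random
  direction, drift $v\,\Delta t$) — no localization noise, confinement
  or motion switching.
* `gen_ring_image()` paints a blurred annulus of known radii.

Passing the closed-loop suites therefore demonstrates estimator
correctness under these explicit models, not robustness to every
real-data artefact.

## Problem sizes and reproducibility

The shipped analyses and tests run at desk scale by choice: synthetic
cells of ~5 µm equatorial radius with up to ~120 particles per stack,
16-cell condition groups, 100-track mixtures, and a 0.125 µm simulation
grid (~29k unknowns). The orchestrated pipeline (`run_manifest()` +
`run_pipeline()`) derives every stage's seed from one master seed, writes
per-cell CSVs, a per-condition summary and a run log, and reproduces all
outputs byte-for-byte on rerun. Group comparisons use the Kruskal–Wallis
rank test with the conventional star annotation.
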