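# mechanopore

Quantitative analysis of microfluidic cell mechanoporation imaging: an R
package plus a numbered analysis workflow for labs that compress
suspended cells in contactless viscoelastic flow, open a transient
equatorial membrane pore, and deliver nanoparticles through it.

## The problem and who this is for

Contactless viscoelastic compression flattens a spherical suspended cell
(semi-axes `a = c`) into an oblate spheroid (`a = b > c`). The membrane
curvature steepens at the equator, membrane tension rises, a
micrometre-scale pore opens there, and for the ~10 minutes before the
cell reseals, nanoparticles enter by passive diffusion. Quantifying that
chain of events takes six different measurements, each with its own
estimator:

* **Cell curvature.** With squared eccentricity `e² = (a² − c²)/a²`, the
  meridian principal radii are `ρ₁ = a(1 − e²)/(1 − e² sin²φ)^{3/2}` and
  `ρ₂ = a/(1 − e² sin²φ)^{1/2}`; curvatures `Cᵢ = 1/ρᵢ` and total
  curvature `J = C₁ + C₂`, maximal at the equator (φ = 0). The
  compression force scales as `F ∝ β³ η λ U²max`.
* **Membrane tension** from FLIM: weighted multi-start biexponential fits
  `I₁e^{−t/τ₁} + I₂e^{−t/τ₂}`, reporting the majority-signal lifetime τ₁.
* **High-tension point maps**: red-channel windowing (120–180), circle
  fit of the cell, normalized polar coordinates, and the largest share of
  points in eight 45° bins against the uniform 12.5% baseline.
* **Actin cortex**: ring thickness `(R_major − R_minor)/2` and
  area-normalized ring intensity.
* **Nanoparticle delivery** from confocal z-stacks: calibrated volumetric
  thresholding, occupied volume / single-particle volume `(4/3)π(d/2)³`,
  delivery efficiency as treated-over-control count ratios, and
  colocalization as an endocytosis proxy.
* **Transport classification** from tracking: time-averaged MSD, power
  law `MSD ∝ τ^α` fitted in log–log, `R² > 0.75` acceptance, `α ≤ 1`
  diffusive vs `1 < α < 2` actively transported.
* **Pore-diffusion simulation**: axisymmetric finite-volume solution of
  Fick's second law with the membrane as an internal barrier and a polar
  pore, Stokes–Einstein diffusivities, backward-Euler stepping with exact
  mass conservation.

Every input modality has a seeded synthetic generator with known ground
truth (`gen_decay()`, `gen_tension_image()`, `gen_zstack()`,
`gen_trajectories()`, `gen_ring_image()`), so the whole pipeline is
testable without microscope data.

## Worked example

The `analysis/` directory holds the numbered drivers; each writes its
tables under `results/` and prints a short summary. For example:

```sh
$ Rscript analysis/01_cell_geometry.R
Control sphere:   C1 = C2 = 0.12 1/um at every angle (1/a)
Compressed cell:  equatorial C1 = 0.25 1/um, J = 0.354 1/um
Curvature steepens at the equator by a factor of 2.08

$ Rscript analysis/02_membrane_tension.R
tau1: Ctrl 4.71 ns, T0 5.30 ns (+12.5%), T1 4.66 ns
Ctrl vs T0: Kruskal-Wallis H = 23.3, p = 1.4e-06 ***
high-tension points: mean normalized radius 1.01 (rim),
max 45-degree bin holds 75% of points on average (baseline 12.5%)

$ Rscript analysis/04_np_delivery.R
delivery efficiency: 200 nm T0 12.6x, T1 6.3x; 500 nm T1 3.0x
```

Reading: the control cell (8.3 µm radius sphere) has curvature
1/a ≈ 0.12 µm⁻¹ everywhere; compression roughly doubles the equatorial
meridional curvature to 0.25 µm⁻¹, which is where the pore opens. The
tension probe's lifetime rises ~12% right after compression and recovers
ten minutes later, with the high-tension points sitting on the cell rim
(normalized radius ≈ 1) and concentrated in one 45° sector. Counting
particles in synthetic z-stacks with planted ground truth recovers the
12×/6×/3× delivery-efficiency design of the treated conditions.

The same stages can be run under one manifest:

```r
library(mechanopore)
m <- run_manifest(seed = 7, outdir = "results/pipeline", n_cells = 3)
res <- run_pipeline(m)   # per-cell CSVs + summary.csv + run_log.txt
```

Reruns with the same seed reproduce every output byte for byte.

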