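---
title: "Quantifying the murine upper airway: segmentation, morphometry, airflow and respiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the murine upper airway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The measurement problem

Craniofacial hypoplasia constricts the upper airway, and in mouse models of
Down syndrome this narrowing is a candidate mechanism for obstructive sleep
apnea. Quantifying it requires combining four measurement modalities on the
same animals: micro-CT airway geometry, landmark-based craniofacial
morphometry, simulated inspiratory airflow, and whole-body plethysmography,
with two-group statistics on top. This vignette describes the models and
numerical choices behind each stage, what the synthetic phantoms do and do
not emulate, and the limitations a user should keep in mind.

## Segmentation model

The airway lumen is a void: in CT it is the darkest structure (~ −1000 HU).
The pipeline therefore *inverts* the volume so the lumen becomes the
brightest structure and then thresholds. The automatic mode applies the
bimodal (Otsu, maximum between-class variance) criterion to the **upper
half** of the intensity distribution. The restriction matters: an inverted
head volume is trimodal (bone, soft tissue, air), and unrestricted Otsu can
place its single split between bone and soft tissue, merging the lumen with
everything else. Restricting to intensities above the median discards the
bone mode and leaves the soft-tissue/air decision, which is the one we want.
A fixed numeric threshold is exposed for sensitivity analyses.

Thresholding is followed by extraction of the 26-connected component
containing a user seed (26-connectivity keeps thin nasal passages intact
where 6-connectivity fragments them) and 2D hole filling per axial slice.
Filling in 2D rather than 3D is deliberate: a genuine side channel is a
"hole" in 3D but not in its own slice, so slice-wise filling removes
reconstruction speckle without sealing real anatomy.

Coordinates follow the voxel-centre convention throughout: the world
position of 1-based index *i* is `origin + (i − 1) · spacing`, all in mm.

## Centerline and curved-reformation morphometry

Published airway studies often trace the central axis manually. For
reproducibility the default here is algorithmic: the lumen voxel graph
(26-neighbour, physical chord lengths) is weighted by the inverse square of
the grassfire interior depth — voxels deep inside the lumen are cheap, those
hugging the wall expensive — and Dijkstra's algorithm connects the two
endpoints. This medial-weighted shortest path is the skeleton-free
equivalent of "skeletonise, then walk the skeleton", and it satisfies the
same contracts (on-axis within one voxel for straight tubes, arclength
within 3% on a quarter-torus) without a 3D thinning dependency. A
user-supplied polyline is accepted anywhere a centerline is, so manual axes
remain usable for parity work.

The raw voxel path is smoothed with a moving average over 0.2 mm of
arclength — enough to suppress voxel-scale jaggedness, an order of magnitude
below the 1 mm station spacing so curves are not short-cut.

Cross-sections are measured perpendicular to the local tangent by
nearest-neighbour resampling on an in-plane grid at half the voxel spacing,
keeping the in-plane connected region that contains the centerline point
(area = pixel count × pixel area). This is the quantity a curved
multiplanar reformation measures, and it is distinct from the inflated
ellipse an oblique axial slice would give: at the native 20 µm voxel scale a
cylinder tilted 30° to the grid still reads within 2% of πr², not the 15%
larger oblique area. Station batteries are anchored at the caudal edge of
the hard palate with positive labels rostral (default +3 … −5 mm at 1 mm
intervals, nine stations).

Segment accounting assigns every lumen voxel to the arclength of its
nearest centerline point (the polyline is densified to half a voxel first so
assignments do not alias): the nasal compartment runs from the nostrils to
the hard-palate edge, the pharyngeal compartment from there to 5 mm caudal,
and the two are exactly additive by construction. Whether the "nasal
cavity" should end at the meatus merge instead of the hard-palate edge is
not standardised; we chose the hard-palate edge and report the meatus-merge
station separately in the flow summary, so either convention can be
reconstructed.

## Airflow model

The simulated condition is peak inspiration: steady, Newtonian, homogeneous,
incompressible flow at a constant volumetric rate (default 5.28 ml/s, a
cohort-mean peak inspiratory flow applied identically to every airway so
that pressure differences reflect geometry alone), with the nostril pressure
fixed at 0 Pa. Air properties default to 20 °C values (ρ = 1.204 kg/m³,
μ = 1.825 × 10⁻⁵ Pa·s) and are configurable.

**Quasi-1D solver.** Along the area profile A(s),

$$P(s) = P(0) - \tfrac{1}{2}\rho\left[(Q/A(s))^2 - (Q/A(0))^2\right]
 - 8\pi\mu Q \int_0^s \frac{du}{A(u)^2},$$

i.e. inviscid Bernoulli exchange plus the Poiseuille loss of the circular
tube with the same local area, with trapezoidal quadrature for the viscous
integral. On a straight tube this reduces algebraically to Hagen–Poiseuille
(8μLQ/πR⁴), which the tests verify to quadrature accuracy. For phantom work
the profile can come either from perpendicular sections or from
`arclength_area_profile()`, which differentiates binned voxel volume with
respect to arclength over an overlapping window (default max(2 × step,
4 voxels)); the windowing suppresses voxel-layer aliasing, and paired nasal
passages contribute their areas in parallel, which is the correct
reduced-order treatment of two nostrils carrying one flow. For that reason
the pipeline evaluates the flow profile against the straight landmark
midline rather than the medial path, which necessarily runs inside one
nostril in the paired region.

**3D solver.** A staggered (MAC) finite-volume discretisation on the lumen
voxels: velocity components on cell faces, pressure at cell centres,
pseudo-transient projection iterations to steady state. Diffusion is
implicit (the three momentum operators and the pressure Poisson operator are
assembled once and Cholesky-factored via the Matrix package, so each
iteration is four triangular solves), advection is explicit first-order
upwind, and each step ends with a pressure projection that enforces
divergence-free velocities to machine precision. No-slip walls impose the
tangential condition at the half-cell via ghost antisymmetry, so the
effective wall lies on the voxel face. The inlet is an open pressure
boundary (ghost Dirichlet at the face, velocity driven by the projection);
the outlet delivers the prescribed flow through a Dirichlet face whose
profile is, by default, extrapolated from one cell inside and rescaled to
exactly Q each iteration. The extrapolated profile was chosen over a flat
one after the flat profile proved to add an artificial redistribution
pressure drop of roughly half a diameter's equivalent length; with
extrapolation the end-effect on the tube benchmark is below 0.5%. The time
step defaults to 0.4 h / (peak_factor × outlet speed); `peak_factor` guards
the advective CFL condition and should be raised for strongly constricted
geometries. Convergence is declared when the maximum relative velocity
change per pseudo-step falls below `grid_tolerance`.

The solver is laminar by design: at 5.28 ml/s through ~1 mm² sections the
Reynolds number is a few hundred, and a warning is issued above 2000. No
turbulence closure is attempted.

Validation uses the staircase-voxelised cylinder. Its genuinely rough
boundary costs extra dissipation of order the voxel size, so the
pressure-drop error against smooth-tube Hagen–Poiseuille decreases from ~9%
at 8 voxels/diameter through ~8% at 16 to ~3.4% at 32, while the parabolic
peak-to-mean ratio of 2 and exact per-section flux hold at all resolutions.
The benchmark tube uses 32 voxels/diameter and a length of 5 diameters
(~160k lumen cells, a few minutes on one CPU); these sizes are the
package's validation conditions, stated here so they can be reproduced.

**Summaries.** Vmax is reported per region (nasal cavity = nostrils to
meatus merge; pharyngeal airway = hard-palate edge to epiglottis; the span
between the two landmarks is the hard-palate segment). Pmax is the
*station-averaged* pressure at the epiglottis — robust to single-voxel
extremes — with the pointwise minimum reported alongside for the 3D solver.
The region within two hydraulic diameters of the outlet is excluded from
Vmax extraction to avoid the Dirichlet-face artefact. Segment drops
telescope exactly: P_nasal + P_hard + P_soft = Pmax − P_inlet.

Because commercial-solver meshes, schemes and any turbulence settings used
in published studies are generally unreported, absolute Pa and m/s values
from other software are not parity targets; directional and closed-form
properties are.

## Plethysmography model

Breathing is scored only during quiet wakefulness: maximal movement-free
intervals of at least 5 s (inclusive). Breaths are delimited by
hysteresis-guarded zero crossings of flow — a crossing counts only after
flow exceeds a guard band of 5% of the robust (95th percentile) amplitude,
which stops noise from splitting breaths — with the actual boundary refined
by linear interpolation. Breaths not wholly inside one quiet epoch are
discarded whole rather than truncated. Episodes with computed tidal volume
below 0.05 ml or above 2.0 ml are excluded (strict inequalities; boundary
values are retained). Respiratory rate divides the breath count by the
extracted time, which defaults to the summed duration of the retained
breaths — this makes the rate insensitive to incomplete breaths at epoch
borders; minute volume is tidal volume × rate by definition. On noiseless
synthetic traces all seven parameters are recovered within 2% across tidal
volumes 0.05–0.5 ml and rates 60–300 /min.

## Group statistics

Every two-group comparison uses Welch's unequal-variance t-test with
Welch–Satterthwaite degrees of freedom, two-sided, α = 0.05, and no
multiple-testing adjustment — matching how such physiology tables are
conventionally reported (a Holm option exists). The summary-statistic entry
point matters: published tables print mean, SD and n but not raw data, and
`welch_from_summary()` reproduces P values directly from them. Printed
summaries are themselves rounded, so a recomputed p can differ from a
printed p by a few units in the third decimal; the package's acceptance
tests treat a printed p as reproduced when it lies within the interval
spanned by perturbing each printed summary inside its rounding half-width.

Missing data are excluded per measure, not per subject (losing one animal's
bone battery should not discard its soft-tissue measures), and a measure
with fewer than two valid subjects in a group is flagged untestable rather
than tested.

## What the phantoms emulate — and what they do not

The generators produce: solid digital cylinders (straight, tilted, curved
along a torus arc) and venturi constrictions with exact analytic area,
volume and length; a parametric "mouse upper airway" — a tube whose
cross-sectional area follows a configurable profile (defaults echo an adult
wild-type mouse: ~18.6 mm³ nasal cavity, ~5 mm³ pharyngeal volume, 5.8 mm
pharyngeal length, narrowest section 1 mm caudal to the hard palate),
optionally split rostrally into paired nasal passages sized so the union of
the two lobes realises the configured area exactly, with six functional
landmarks (nostrils, meatus merge, hard-palate edge, epiglottis, arytenoid);
half-sine breathing traces with analytic tidal volume, timing and peak
flows; and two-group normal cohorts with specified moments. The CT-like
intensity model is three-valued (air −1000, soft tissue 0, bone +1000),
which exercises the inversion-threshold-connectivity chain.

They deliberately do not emulate CT physics (beam hardening, noise spectra,
partial-volume blur), real turbinate anatomy (the supplementary landmark
anatomy of published studies is not available, so landmarks are functional,
not anatomical), respiratory motion, or airway wall compliance. Passing
tests therefore demonstrate that the *measurement and simulation machinery*
is correct on known geometry — not that any given biological claim
transfers; on real data the segmentation threshold and manual clean-up
remain the dominant unquantified uncertainty.

A uniform cross-section scale factor (areas × k²) provides a one-parameter
"genotype" knob: at fixed inspiratory flow a 0.8× airway must show a
strictly deeper epiglottic pressure, and both solvers reproduce that
direction.

## Numerical choices and degenerate inputs

* Inversion is exact negation (an involution); geometry never changes.
* Raising a fixed threshold never adds voxels (monotonicity is tested).
* A seed point in solid tissue, endpoints in disconnected lumen components,
  a single-point centerline, landmarks projecting out of order, stations
  outside the centerline, zero or negative areas in a flow profile, and an
  empty breath table all raise typed errors; empty volume regions return 0
  with a warning.
* Cross-section planes clipped by the volume boundary are measured over the
  in-volume part and flagged `truncated`, with a warning.
* Degenerate Welch inputs (both SDs zero) return p = 1 for equal means and
  p = 0 with a warning otherwise.
* All generators are pure functions of (configuration, seed); the pipeline
  is byte-reproducible given (config, seed).

## Known limitations

* The 3D solver's staircase walls limit absolute pressure accuracy to a few
  percent at 32 voxels/diameter; sub-voxel (cut-cell) boundaries are out of
  scope.
* The quasi-1D model has no entrance, curvature or separation losses, so its
  absolute pressures are lower bounds in magnitude; it is used for
  directional and closed-form checks and as the venturi oracle.
* Landmark placement on real scans is manual and outside the package; only
  the distance battery and statistics downstream of placement are covered.
* The plethysmograph's chamber-physics conversion (pressure to volume) is
  assumed done by the instrument; traces must arrive calibrated.
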