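---
title: "Methods: strut protrusion, flow and shear-stress assessment of bioresorbable scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strut protrusion, flow and shear-stress assessment of bioresorbable scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strutflow)
```

# The problem

When a bioresorbable scaffold (BRS) is implanted in a coronary artery, its
struts stand proud of the vessel wall and disturb the near-wall blood flow.
Endothelial shear stress (ESS) — the tangential viscous force per unit area
that flowing blood exerts on the lumen, in pascal — is the read-out that
links this disturbance to biology: laminar, moderately high ESS keeps the
endothelium quiescent, while low (< 1.0 Pa) and very low (< 0.5 Pa) ESS
promote inflammation, neointima and thrombosis. Two quadratic-strut designs
are compared throughout: a thick-strut device (157 um struts, 176 um wide,
1.0 mm inter-strut distance, 27% vessel coverage) and a thin-strut device
(95 um, 170 um wide, 1.4 mm, 29%).

`strutflow` implements the full assessment pipeline at desk scale:

1. **synthetic data** — vessel phantoms, OCT-style pullbacks and biplane
   projections with known ground truth;
2. **OCT analysis** — flow-area contours, per-strut protrusion and
   apposition, aggregation to 200 um intervals / cross-sections / device;
3. **reconstruction** — 3D centerline from two angiographic projections,
   rotation-minimizing frames, perpendicular contour mounting;
4. **hemodynamics** — steady incompressible Newtonian flow with struts as
   immersed obstacles, wall shear stress extraction;
5. **ESS mapping** — 5-degree x 200-um sectorization, low/very-low
   classification, summaries;
6. **statistics** — univariate tests and the three-level mixed model.

The numbered scripts under `analysis/` run these stages as a narrative
workflow and write their tables under `results/`.

# Synthetic data: what it emulates and what it does not

No in-vivo data ship with the package; every downstream stage is validated
against generated phantoms whose ground truth is known exactly.

A `vessel_phantom()` is a straight, arc or helical centerline with constant
lumen radius, one seeded side-branch landmark and
proximal-native / scaffolded / distal-native segment bounds (default 2 mm
native margins). `simulate_pullback()` samples lumen contours at 1-degree
angular resolution — finer than the 5-degree ESS sector grid, which is why
that resolution was chosen — at a configurable frame spacing. The pullback
device's frame spacing is not a physical constant of the problem, so it is
a parameter; the default of 200 um matches the protrusion-analysis
interval. Strut rings are laid along the scaffolded segment with ring pitch
equal to the *clear* inter-strut distance plus the strut width; we read the
device's quoted inter-strut distance as the clear wall gap between
consecutive ring edges, since that gap is what the flow sees. Struts have
rectangular cross-sections (square corners, no fillets), and the adluminal
edge sits at `wall - protrusion_fraction * thickness`; fractions above 1
lift the abluminal edge off the wall and create malapposed struts
(fractions above 1.2 are rejected). Per-strut protrusion jitter is
available but defaults to 0 so geometric examples stay exact.

The generator does **not** emulate OCT speckle, catheter eccentricity,
cardiac-motion gating, tissue prolapse between struts, vessel taper or
non-circular lumens. Passing round-trip tests therefore demonstrates that
the *measurement chain* is correct, not that it is robust to real-image
artifacts.

`simulate_hierarchical_ess()` is the generative twin of the statistical
model: sector ESS = grand mean (0.73 Pa) + type effect (0.79 Pa for the
thin-strut type, chosen so the two expected in-scaffold means are 0.73 and
1.52 Pa) + Gaussian random intercepts for animal, scaffold and
cross-section + sector noise. The default layout mirrors a 9-animal,
12-scaffold study in which type varies between animals (six animals with
one thick-strut device, three with two thin-strut devices); defaults use 8
cross-sections per scaffold and 72 sectors per cross-section. Default
random-effect SDs (0.2 / 0.1 / 0.1 Pa) and sector SD (0.5 Pa) were set
once to give realistic intra-class correlation at these levels.

# OCT protrusion analysis

The flow area of a scaffolded frame is bounded by the adluminal strut
edges and the wall between struts; `build_flow_area_contour()` implements
exactly that substitution and rejects overlapping spans and inverted
geometry. Protrusion distance is (interpolated wall radius across the strut
footprint) minus the adluminal radius, floored at zero; the wall under a
strut is linearly interpolated in polar coordinates between the contour
samples flanking the span — the simplest reproducible stand-in for
semi-automated tracing. Open design points were resolved as follows:

* **Malapposition criterion**: abluminal-edge-to-wall gap strictly greater
  than 20 um, roughly the axial resolution of frequency-domain OCT. A gap
  exactly at the tolerance is *not* malapposed.
* Malapposed struts are excluded from protrusion statistics (protrusion is
  reported as a percentage of thickness at or below ~100%, which implies
  apposed-only statistics).
* Axial intervals are half-open `[k*200, (k+1)*200)` um, 0-based at the
  first scaffolded frame, so every apposed strut lands in exactly one
  interval.
* Reported protrusion fractions are rounded to integer percent to match
  the precision conventionally printed.

# Reconstruction

Projection geometry is orthographic (parallel-beam): no cone-beam
calibration data exist for a desk validation, and a self-consistent
forward/inverse pair is all the round trip requires. A point maps to
`u = x cos(angle) + y sin(angle)`, `v = z` for gantry angle about the
patient axis; pairs closer than 25 degrees are rejected, mirroring the
exclusion of non-reconstructable cases.

Point correspondence between the two views deserves a note. The generic
prescription is pairing by normalized arc length, but in this projection
geometry both views share the axial image coordinate, so the epipolar
curves are exactly the horizontal image lines: when both polylines are
monotone in `v`, pairing on a common `v` grid is the geometrically exact
correspondence, and it reduces the helix round-trip error from ~3% of
segment length (arc-length pairing) to well below 0.1%. The package uses
the epipolar pairing when it is valid and falls back to arc length for
non-monotone polylines.

Local frames are rotation-minimizing (double-reflection method): tangent
continuity, no axial flips, constant frames on a straight line, and a
drift relative to the Frenet frame at exactly the torsion rate (tested on
a helix to 2%). Contours are mounted rigidly — perimeter and area are
preserved — in the normal plane at their arc length, at 100 um spacing in
the scaffolded segment and 400 um in the native segments, interpolating
between available frames but refusing to interpolate finer than 4x the
frame spacing. Absolute orientation uses one global rotation, the circular
mean of (angiographic minus OCT) landmark angles; torsion correction per
frame is out of scope.

# Hemodynamics

The primary solver mode is a 2D axisymmetric (longitudinal-radial)
finite-volume model on a staggered uniform grid with SIMPLE
pressure-velocity coupling, written in C++ for speed. Strut rings enter as
stair-step immersed rectangular obstacles with no-slip faces. This is a
deliberate surrogate for a full 3D solver: the study restricts itself to
straight segments, where ring-symmetric struts capture the mechanism under
investigation (flow separation and WSS recovery between struts) at a cost
that allows the whole pipeline to be tested in minutes.

Blood is homogeneous and Newtonian, viscosity 0.0035 Pa.s, density
1050 kg/m^3; the wall is rigid with no-slip; the outlet is zero-gradient
at reference pressure 0. The inlet profile defaults to parabolic (fully
developed); the measured quantity is only the *mean* inflow velocity, so
the profile shape is a declared choice, with a flat option that prepends a
10-diameter entrance length. Inlet velocity can be estimated from contrast
transit (`Q = volume x frame rate / frames`). Solutions with Reynolds
number above 2000 are rejected as outside laminar validity.

Numerical choices: first-order upwind convection with central diffusion;
under-relaxation 0.7 (velocity) / 0.3 (pressure); convergence when the
normalized momentum-plus-continuity residual falls below 1e-6 (cap 10,000
outer iterations; non-convergence is a warning carrying the residual
history, never silently accepted). The mesh edge targets one fifth of the
strut thickness times a `coarsening` factor; `coarsening = 1` reproduces
the full near-strut density, and the desk-scale default of 2 is logged via
a message. Exceeding the explicit cell budget is an error rather than a
silent coarsening. WSS is `mu * |du_t/dn|` one-sided into the fluid at the
topmost fluid cell of each axial station (distance `dr/2`); the signed
near-wall velocity is kept for recirculation diagnostics. On the strut-free
cylinder this reproduces the Poiseuille value `4 mu v / R` to ~0.1% at
desk resolution, and the error decreases monotonically with refinement.

Problem sizes used by the tests and the acceptance script — stated here as
the package's chosen desk scale: tubes of 8-14 mm length, radius 1.5 mm
(the 3.0 x 14 device), coarsening 2 (edge 63 um for 157 um struts, 38 um
for 95 um), 4-15 x 10^3 cells, converging in 400-1600 iterations.

## The inter-strut recovery surface

The design rule that the inter-strut distance should be at least six times
the strut thickness is checked arithmetically by
`interstrut_recovery_check()`. Its hemodynamic counterpart — midpoint WSS
recovering to at least 80% of the strut-free value at 6x spacing and
failing to at 3x — holds only partially in this model at the protrusion
levels the devices actually exhibit. With square ribs at full protrusion
(height = thickness, Re ~ 135), measured midpoint recovery is ~0.2-0.55
at 6x spacing and refinement lowers it: a gap-to-height ratio of ~6 sits
at the classical d-/k-type roughness boundary, where flow reattaches
between ribs (the 3x case correctly stays below any recovery threshold)
but the redeveloping boundary layer does not regain 80% of the smooth-wall
shear; that requires gap/height of roughly 15-20, or struts embedded to
about half their thickness (measured recovery 0.84 at 50% protrusion).
The 6x rule is therefore best read as a reattachment condition, not a
magnitude-recovery guarantee. The acceptance suite keeps the 80% bound as
written and reports the measured ratios; the corresponding test fails by
design rather than moving either the threshold or the study conditions.

# ESS mapping

Wall elements are binned into half-open cells of 5 degrees x 200 um
(72 sectors exactly). Cells average element WSS weighted by element *area*
— whether the original in-house binning weighted by area or node count is
unknowable, so area weighting is declared and tested. Empty cells are
missing (NA), never imputed as zero. Classification is strict: `ess < 1.0`
is low, `ess < 0.5` is very low (nested), a value exactly at a threshold
is neither. Sector angles live in the mounted frame fixed by landmark
orientation, so sectors are anatomically consistent along the vessel.
Summaries report mean/SD and median; the median is the per-cross-section
statistic used for distribution displays, the mean for device-level
tables, and both are emitted.

# Statistics

The inferential model is the linear mixed model

```
ess ~ scaffold_type * cross_sectional_area +
      (1 | animal) + (1 | animal:scaffold) + (1 | animal:scaffold:cross_section)
```

fitted by **maximum likelihood** (not REML), because candidate models are
compared by their likelihoods; random effects are nested intercepts only,
matching a design that lists three random ID terms without slopes. Sector
observations are the residual level; cross-sectional area enters raw
(uncentered) — centering changes only the intercept's interpretation here,
and sensitivity to it is limited to that term. Fixed-effect p-values are
Wald t tests with Satterthwaite degrees of freedom via lmerTest (recorded
in the result; a normal-approximation fallback is available and likewise
recorded). Singular fits and non-convergence are flagged, never silently
dropped. `select_model()` ranks by log-likelihood, applies likelihood-ratio
tests to nested pairs, reports AIC for non-nested ones, and breaks exact
ties toward fewer parameters.

Calibration at the study's grouping scale (9 animals, 12 scaffolds, type
varying between animals) was verified by simulation: the injected 0.79 Pa
type effect is recovered within two standard errors, and 200 null
replicates give a Wald-test size within 5% +/- 3%. The null replicates use
reduced within-unit sizes (6 cross-sections per scaffold, 12 sectors per
cross-section), a deliberate choice: test size for a scaffold-level effect
is governed by the number of scaffolds and animals, which are kept at
study scale, not by the residual-level count.

# Known limitations

* The axisymmetric solver cannot represent helical/offset strut cells,
  side-branch outflow, curvature-induced swirl, or circumferential ESS
  variation from non-circular lumens; in axisymmetric runs all 72 sectors
  of a ring carry the same ESS, so sector maps exercise the binning
  contract rather than circumferential physics.
* Stair-step immersed boundaries quantize protrusion depth to the radial
  cell size; neighboring depths can tie at desk resolution.
* Steady flow only: no pulsatility, no oscillatory shear metrics; rigid
  wall; Newtonian rheology.
* In-vivo ESS magnitudes (0.73 vs 1.52 Pa) derive from animal data that
  are not public; the pipeline reproduces the *direction and mechanism*
  of that contrast on matched synthetic vessels, not the printed values.
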