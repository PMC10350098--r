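---
title: "Modelling brass aperture blocks in a virtual-particle proton Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling brass aperture blocks in a virtual-particle proton Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pencil beam scanning proton therapy (PBSPT) delivers dose as thousands of
magnetically steered, individually weighted beamlets (spots). For
stereotactic radiosurgery (SRS) of small, shallow brain targets the lateral
dose fall-off of the individual beamlet is the limiting factor: shallow
targets need an upstream range shifter to pull the Bragg peaks back, and the
extra Coulomb scattering in the shifter inflates the in-air spot sigma from
a few millimetres to beyond a centimetre. A patient-specific brass aperture
block — 30 mm thick, with an opening milled to the target silhouette plus a
margin — restores a sharp penumbra, but only if the dose engine actually
models it. The small openings involved (down to 1 cm) defeat voxelized
collimator models, so the opening must be represented by its exact polygon
boundary.

This package implements that capability end to end in two Monte Carlo
engines plus the planning loop around them: physics-table generation,
condensed-history transport, polygon-opening geometry, 3D gamma validation,
and scenario-based worst-case robust optimization of spot weights. All
studies run on synthetic water/brass phantoms built in code.

## The two engines

Both engines transport proton-like particles in condensed-history steps of
at most 1 mm (never straddling an axial component boundary) and share one
geometry model: range shifter slab, brass block slab with a polygonal
opening, and a voxelized relative-stopping-power (RSP) phantom. Per step
they sample

* mean energy loss from a Bethe stopping-power table (MeV/mm),
* Gaussian energy straggling with the Bohr sigma (MeV/sqrt(mm)),
* a Highland multiple-scattering deflection (rad/sqrt(mm)), and
* a nuclear removal event (probability/mm).

The **reference engine** (`mc_simulate()`) is a conventional MC: primaries
are transported one at a time and a nuclear event removes the primary,
deposits part of its energy locally and spawns a secondary proton that is
transported recursively. It is the in-repo anchor against which the VP
engine is validated, and it doubles as the history source for fitted-mode
physics tables.

The **virtual-particle (VP) engine** (`vp_simulate()`) creates every
particle of the run before transport begins: one VP per primary, plus one
pre-assigned secondary VP for each primary whose nuclear conversion is
pre-sampled at initialization. The conversion point comes from combining an
Exp(1) variate with the cumulative nuclear interaction depth along the
primary's straight-line path (mean energy loss only); the secondary VP
starts at that point with half the local energy and a wide-Gaussian
(sigma = 0.2 rad) emission angle, and the primary carries the matching
deterministic deactivation depth, at which it deposits its remaining energy
and stops. After initialization the per-step update rule is *identical for
every VP*: the same table lookups and the same three Gaussian draws are
executed regardless of material or particle generation — air and the
aperture opening use zero-valued tables, so a VP there simply advances with
unchanged energy and direction. `step_vp()` exposes this rule directly and
instruments the operation counts, which are asserted constant across
materials in the test suite; this operation-uniformity is the property that
makes the VP formulation trivially parallelizable on wide SIMD/GPU hardware,
although this implementation runs it in portable compiled code.

Because the secondary placement uses the straight-line energy profile
rather than the scattered path, VP secondaries are displaced by roughly the
lateral scattering scale (a few mm) relative to reference-engine
secondaries. Secondaries carry only a few percent of the dose, so the
effect stays inside the gamma-validation envelope; it is the main known
approximation of the VP conversion.

## Geometry and the crossing-number opening test

Isocenter is the origin and the beam travels along −z. The default mount
puts the block's downstream face 150 mm from isocenter (slab z in
[150, 180] mm); the range shifter (45 mm water-equivalent, modelled as a
45 mm water slab of 6.1 cm diameter) sits with its downstream face at
190 mm, leaving a 10 mm gap. Inside the block slab a particle is classified
as *opening* or *brass* by the crossing-number (ray casting) algorithm on
the opening polygon, with the standard half-open vertex rule (a vertex
counts as a crossing iff its y strictly exceeds the test point's y) so that
edge-touching points classify deterministically. Circular openings are
inscribed 64-gons (area deficit ~0.16%). Patient-specific openings follow
the clinical margin recipe in `opening_from_target()`: target mask + 1 mm
isotropic (PTV) margin, beam's-eye-view projection, + 2 mm lateral margin;
the returned polygon is the convex hull of the dilated silhouette, which is
simple by construction and contains every dilated target pixel, at the cost
of over-covering concave or multi-lobe silhouettes.

## Physics models and tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Energy grid | 0–230 MeV in 0.5 MeV bins | covers the machine span 71.3–228.8 MeV with interpolation error far below straggling noise |
| Step length | 1 mm | matches the 1 mm validation dose grid; boundary-limited near slabs |
| Energy cutoff | 1 MeV | residual range < 0.03 mm; remainder deposited locally |
| Brass | Cu 70 / Zn 30, 8.50 g/cm³ | common cartridge brass; the block alloy is not otherwise constrained |
| Water I-value | 75 eV | standard; gives CSDA ranges within ~1% of reference tabulations |
| Highland log-term | frozen at 1 mm reference step | exact sqrt(step) scaling keeps both engines' sampling consistent under step subdivision |
| Nuclear removal | 0.001/mm × density above 20 MeV | ~1% of primaries per cm of water; reproduces dose build-up and the post-peak tail |
| Secondary model | fraction 0.5 of energy, sigma 0.2 rad | simplest model producing a realistic broad secondary halo |
| In-air sigma | 5.0 mm at 71.3 MeV → 2.0 mm at 228.8 MeV, linear | machine beam model anchors |

With these choices 30 mm of brass stops protons up to ≈156.6 MeV (the
engineering statement behind the block thickness: every clinical energy for
shallow targets is blocked), and the Bragg-peak depths land within the
validation tolerance (3 mm) of the CSDA range across the machine span.

The tables can also be *fitted* from recorded condensed-history samples
(`record_material_histories()` + `generate_tables(mode = "fitted")`), which
mirrors how a production engine derives its tables from a full-physics
reference code. Fitted values calibrate the analytic shape by per-node
ratios, so table invariants (monotone mean energy loss over the machine
span) survive fitting noise; agreement is within 5% at 1e5 histories per
node and 2% at 1e6.

## Dose scoring, uncertainty and gamma analysis

Dose grids are per-unit-total-spot-weight energy deposits on the phantom
voxel grid, accumulated in (default 10) independent batches; the per-voxel
relative standard error across batches is attached, and the run's headline
uncertainty is the mean relative SE over voxels above 50% of the maximum
(a convention choice; the underlying per-voxel map is always available).
RNG streams are counter-based per history, so results are bit-reproducible
for a fixed seed and independent of execution order.

`gamma3d()` implements global 3D gamma: the dose-difference criterion is a
percentage of the *reference* maximum (the asymmetry is deliberate and
tested), the search is capped at 3× the DTA with trilinear subsampling at
DTA/10, and early termination on a distance-sorted offset list makes the
exhaustive minimum exact within the cap. The test suite pins the pass rate
against a dense brute-force oracle; offsets beyond one DTA cannot produce
gamma ≤ 1, so the cap cannot change a pass/fail decision.

## Validation studies and problem sizes

Two studies compare the VP engine against the reference engine, chosen as
this package's standing validation surface:

* **Single beamlets**: 1 cm opening, beamlet aimed at the opening edge,
  six energies spanning 71.3–228.8 MeV (including the low/medium/high
  illustration energies 82.0, 140.2, 228.8 MeV) on both machines (AP,
  APRS), 2e5 primaries per engine and case on a 1 mm grid. Pass-rate
  criterion 2%/2 mm with a 10% threshold.
* **Energy layers**: ConfigA (147.0 MeV, no shifter) and ConfigB
  (161.5 MeV, 45 mm WET shifter), openings 1–4 cm, equal-weight spots on a
  2.5 mm grid covering the opening + 5 mm margin, 8e5 primaries per engine
  and scenario; the ConfigA 1 cm case also yields the entrance-region IDD
  mismatch (depths shallower than 80% of the Bragg-peak depth) relative to
  the Bragg-peak IDD.

The particle counts are the package's chosen study sizes: they put the
high-dose per-voxel uncertainty at the few-percent level, which the
DTA-based gamma comparison absorbs (uncorrelated voxel noise rarely defeats
a 2 mm DTA), while keeping the full suite runnable on one CPU core in tens
of minutes. `scripts/acceptance.R` re-runs both studies from scratch.

What the synthetic studies do *not* probe: patient heterogeneity (only the
slab/toy-head phantoms exercise non-water RSP), divergent or
energy-layer-specific apertures (out of scope by design), neutron/photon
transport, and dose-to-medium conversion — everything is dose-to-water in
RSP geometry. Passing gamma here therefore demonstrates engine-vs-engine
consistency of the aperture model, not absolute dosimetric accuracy in
patients.

## Robust optimization

Setup uncertainty (±2 mm along each axis, implemented as the equivalent
rigid beamline translation so phantom-frame masks stay valid) and range
uncertainty (±3% RSP scaling) combine into 13 scenarios (nominal + 6 × 2).
Per scenario and spot, one MC run at unit weight fills a column of a sparse
influence matrix over the optimization region (entries below 1e-4 of the
matrix maximum are pruned; per-entry standard errors are kept alongside).

The objective is a worst-case composite: each dose-volume constraint
contributes a one-sided quadratic penalty evaluated on its own worst
scenario — coverage constraints (V100 ≥ 99%, Dmin ≥ 90%) on the
lowest-coverage scenario, upper limits (CI100 ≤ 1.5~2.0, RHI100 ≤ 1.3~1.4)
on the highest-violation scenario. Coverage penalties aim 5% above their
level to buy margin against the worst case; the conformity surrogate
suppresses dose above 80% of prescription outside the target. The solver is
projected gradient descent with Armijo backtracking: weights stay
nonnegative by projection and the objective is non-increasing over accepted
iterations (both are asserted in tests, and a toy problem with a known exact
solution is recovered to 1e-4 against an independent bound-constrained
solver). Hard-limit compliance is reported for the nominal plan — the
convention of the constraint tables this mimics — while the per-scenario and
worst-case indices are tabulated by `evaluate_robust()`.

A sizing consequence worth knowing: demanding *worst-case* V100 ≥ 99% under
±2 mm shifts forces the nominal 100% iso-volume about 2 mm beyond the
target, so nominal CI ≥ ((r+2)/r)³. For targets below ~8 mm radius this is
arithmetically incompatible with CI ≤ 2.0; the bundled toy robust plan uses
a 9 mm (3.1 cc) target, consistent with the target sizes this workflow is
used for clinically.

## Numerical choices and degenerate inputs

* Out-of-span table lookups clamp to the grid edge (straggling can carry an
  energy marginally below zero between steps); the R-level `lookup()` warns.
* Polygons are validated at construction (≥ 3 distinct vertices, no
  self-intersection); the point test itself never raises.
* A particle exceeding 20 000 steps is a runaway error with a state dump.
* Zero-weight spots are dropped from history allocation; an all-zero spot
  list, an empty SOI mask, an all-zero reference grid, or an empty
  above-threshold set are errors, not silent results.
* MetaImage I/O checks that the raw payload length matches the header.

## Known limitations

* The VP conversion (activation-depth scheme) is a documented stand-in
  validated through the gamma surface, not a reproduction of any specific
  production implementation.
* The nuclear model removes primaries with a single energy-independent
  cross-section and one secondary generation; no heavy fragments, deltas,
  or neutrons.
* Lateral scattering in heterogeneous phantoms scales the water tables by
  sqrt(RSP), a first-order approximation that ignores Z-dependence of the
  radiation length.
* Apertures are non-divergent and laterally infinite outside the opening.
* Concave opening silhouettes are convexified by `opening_from_target()`.
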