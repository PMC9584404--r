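---
title: "leptoflow: model, parameterization, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{leptoflow: model, parameterization, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bonefish (*Albula vulpes*) and other Elopomorph fishes broadcast-spawn
offshore and disperse as leptocephalus larvae for weeks to months before
settling into littoral nursery habitat. Where those larvae end up — which
islands they reach, and in what numbers — is the connectivity question
that determines how spawning-site protection translates into recruitment.
Because the larvae cannot be tracked directly, the standard tool is a
biophysical larval dispersal model (LDM): an individual-based model of
larval biology embedded in a Lagrangian particle-tracking engine driven by
archived ocean-model hydrodynamics.

`leptoflow` implements that pipeline end to end as a tested R package:
analytic synthetic ocean fields stand in for an operational hydrodynamic
archive, so every downstream component — spawning-release
parameterization, larval biology, transport, settlement, and the
connectivity statistics — can be exercised and verified against known
truths.

## The dispersal model

### Transport

Particles carry a position (longitude, latitude, depth), an age in days
post spawn (DPS), and an exclusive fate: `alive`, `out_of_domain`,
`dead_beached`, `dead_cold`, `dead_hot`, or `settled`. Each timestep `dt`
(default 10800 s = 3 h, the cadence of the forcing fields) applies, in a
fixed documented order:

1. **Forward Euler advection.** Velocities are tri-linearly interpolated
   in (lon, lat, depth) and linearly in time at the particle, and the
   displacement `u*dt` is converted to degrees at the particle latitude
   (111,320 m per degree latitude, scaled by `cos(lat)` for longitude).
   Great-circle effects at 3-hour step scale are negligible. The timestep
   must respect the fine-scale Courant–Friedrichs–Lewy bound
   `dt <= 0.7 * dGrid / Umax`; `engine_config()` refuses configurations
   beyond it rather than warning silently.
2. **Horizontal dispersion.** A random-walk increment `delta * sqrt(6 Kh dt)`
   per horizontal axis with `delta ~ U[-1, 1]` drawn independently per
   axis. Since `Var(delta) = 1/3`, each component's variance is `2 Kh dt`
   and the ensemble mean squared planar displacement is the 2-D diffusive
   `4 Kh dt`; the amplitude normalization is chosen to make the
   uniform-increment construction match the diffusivity exactly. The
   default `Kh` scales Okubo's empirical ocean-diffusion power law
   (`0.0103 l^1.15` in cgs) to the grid length; for a 3.1 km grid this is
   about 2.1 m²/s.
3. **Vertical dispersion.** The same uniform-increment construction scaled
   by the local vertical diffusivity `kz`, with reflecting boundaries at
   the surface and the local bottom. Reflection is what makes the scheme
   satisfy the well-mixed condition (a uniform depth distribution stays
   uniform under constant `kz`); the test suite verifies this with a KS
   test against the uniform law.
4. **Buoyancy.** A Stokes terminal velocity computed from the ontogenetic
   relative-density schedule (below), applied as an explicit velocity term
   in the depth update. It is suppressed while the DVM clamp is active,
   since the clamp expresses behaviour that overrides passive buoyancy.
   Whether the original host model applied density as a velocity or as an
   equilibrium depth is not documented; the velocity form is the
   physically explicit choice and can be disabled via
   `engine_config(buoyancy = FALSE)`.
5. **DVM clamp, fates, settlement.** Depth is clamped to the top 2 m
   during the settlement competency window; temperature and salinity are
   sampled; thermal, beaching, out-of-domain and settlement rules fire in
   that order. Fates are absorbing: a particle's record is frozen from the
   step its fate is assigned.

Trajectories are recorded every 3 h (a 71-day run yields 569 records per
larva), and the release is replicated across independent iterations whose
seeds derive deterministically from the master seed, so a run is
bit-reproducible.

### Larval biology

* **Ontogenetic buoyancy.** The relative density of a developing
  leptocephalus is read from a two-column schedule mapping developmental
  progress (age / pelagic larval duration) to the ratio of larval density
  to seawater density at the upper thermocline, interpolated piecewise
  linearly and clamped at the ends. The bundled table
  (`extdata/ajaponica_density_schedule_synthetic.tsv`) is a *synthetic*
  reconstruction of the published *Anguilla japonica* ontogeny: its age-0
  node is fixed by requiring standard Stokes' law — with an equivalent
  spherical radius of 1e-4 m (half the observed 2e-4 m hatchling head
  diameter; the drag shape of a laterally compressed larva is ambiguous,
  so the radius is configurable), seawater density 1024.4 kg/m³ and
  dynamic viscosity 0.959e-3 Pa·s — to give the reported ~8.5 m/day
  hatchling ascent rate, and buoyancy decays monotonically to neutral by
  ~80% of the larval duration. Any user table with the same columns is
  accepted.
* **Diel vertical migration.** Settlement-competent larvae (41–71 DPS,
  closed interval at both ends) are held in the top 2 m, independent of
  proximity to settlement habitat.
* **Lethal temperatures.** Strict bounds at 14 °C and 32 °C: a larva
  survives at exactly the bound. Strictness is the reading consistent with
  a larva surviving within 0.02 °C of the cold limit.
* **Onshore mortality.** A pre-competent particle whose grid cell is land
  dies `dead_beached` — a stand-in for life-stage/habitat mismatch, not
  literal stranding. A competent larva contacting land *outside* any
  settlement zone also beaches; competent land contact *inside* a zone is
  resolved by the settlement rule instead.

### Spawning release

The release is parameterized from an observed spawning event by
proportional translation onto the model water column: the upper release
depth preserves the observed ratio of spawning depth to thermocline depth
(63.7/75.9 = 0.8393…, carried at full precision because the published
worked value 41.96 m requires the unrounded ratio), applied to the model
thermocline; the lower release depth sits where the temperature gradient
grows again below the thermocline. Two estimator choices were open:

* **Thermocline depth** is the depth of maximum |dT/dz| by centred finite
  differences on the native levels, refined below level spacing by a
  parabola through the three neighbouring gradient ordinates (the standard
  sub-grid peak refinement; on symmetric profiles it reduces to the node).
  Ties break shallow. Isothermal or constant-gradient profiles are an
  error, never a silent zero.
* **The below-thermocline gradient maximum** is the largest *local*
  maximum of the gradient-magnitude sequence strictly below the
  thermocline, ties shallow, excluding nodes whose centred stencil reaches
  back into the thermocline transition itself. Taking the literal global
  maximum below the thermocline would always return the level immediately
  below it — the thermocline's own decaying flank — which contradicts the
  phenomenon being modelled (a deviation from the consistent decaying
  gradient). When the gradient decays monotonically all the way down, the
  first level below is returned.

Particles are released uniformly in depth over the derived range (gamete
release over the full ascent range, the conservative reading given that
release at the apex alone is unconfirmed) and area-uniformly over the
horizontal stain disc (radius proportional to the square root of a uniform
deviate; default radius 150 m, half the 300 m telemetry detection range).

### Settlement

Settlement zones are island-tagged polygons (GeoJSON). An alive larva
inside a zone during the closed competency window settles on that island;
in-zone presence before 41 DPS has no effect. Containment is even-odd
ray-casting with boundary points counting as inside — zones are
deliberately over-extended beyond the shoreline, so the closed-polygon
convention favours settlement. Overlaps resolve by file order. Settlement
is evaluated on post-step positions: no sub-step crossing detection,
matching a 3-hour discrete check.

## Assessment statistics

Per run the package computes: daily mean fate proportions (which must
partition the release at every day); gridded occupancy densities (exact
counts, natural-log transformed for display; all-steps and final-step
modes); settlement kernel density estimates normalized to a maximum of 1
(Gaussian kernels, normal-reference bandwidth per axis by default — only
the normalization is prescribed, the bandwidth is configurable); the
island connectivity matrix (settled totals and the fraction of iterations
delivering at least one settler); settlement footprints (the set of
islands settled per iteration, with relative frequencies summing to 1);
and per-settler development-environment records.

The **coefficient of dispersal** of a settler is the great-circle
straight-line distance from spawn to settlement divided by the along-track
path length (haversine segments, Earth radius 6371 km — the distance
metric had to be chosen; haversine on the mean sphere is the conventional
one at basin scale). It lies in (0, 1]: 1 is linear transport, values near
0 are circuitous, retained dispersal.

**Island contrasts** of any development-environment variable chain a
Lilliefors normality screen (Kolmogorov–Smirnov with estimated parameters
— the plain KS null would be misspecified), a tie-corrected
Kruskal–Wallis omnibus, Dunn's pairwise z tests with Bonferroni
correction, and Hedges' g (Cohen's d on the pooled SD times
`J = 1 - 3/(4(n1+n2) - 9)`) with seeded percentile-bootstrap confidence
intervals (default 2000 resamples) and Cohen magnitude classes with
exclusive lower bounds: negligible (< 0.2), small (< 0.5), medium (< 0.8),
large (>= 0.8). Larvae are treated as independent in all of this despite
sharing iterations — a simplification inherited from the analysis being
reproduced, and worth remembering when interpreting p-values.

## The synthetic ocean

`field_scenario()`/`render_field()` compose analytic ingredients into a
4-D field: uniform currents, solid-body or Rankine gyres (rendered on a
local f-plane so rigid rotation is exactly divergence-free on the grid),
two-layer tanh temperature columns with optional secondary deep steps,
constant salinity, constant or depth-profiled vertical diffusivity, and
half-plane or circular-island coastlines rasterized to the land mask.
Fields are steady unless the caller supplies time-varying arrays, and land
cells carry no finite values.

What this *emulates*: the structures the analysis depends on — a
stratified column with a detectable thermocline, mesoscale retention
features, boundary-current export, and coastlines that kill or settle
larvae. What it does *not* emulate: data-assimilative mesoscale
variability, tides, vertical shear of real boundary currents, sigma-grid
artefacts, or shoreline complexity. Tests passing on these fields
therefore verify the *machinery* (integration, sampling, bookkeeping,
statistics), not the realism of any particular dispersal forecast.

## The retention experiment

`retention_experiment()` probes the qualitative signature that proximal
settlement is associated with retention: a Rankine gyre sits beside the
release, a background jet carries unretained larvae to a distal island B,
and island A occupies the western band of the gyre's orbit annulus. The
release stain (5 km, a scenario parameter — not the observational 150 m
stain) is placed *on* the annulus, 25 km west of the centre, so retained
larvae orbit at a fixed radius: their settlement abundance on A rises with
gyre strength as the closed-streamline region engulfs the release, and
their dispersal paths lengthen with orbital speed, driving the coefficient
of dispersal down. Keeping the release radius fixed is what isolates the
orbital-speed effect; releasing across the whole gyre confounds it with a
changing mix of settler orbit radii.

## Numerical choices and degenerate inputs

* Metres–degrees conversion uses the local spherical scaling; gyre
  *rendering* freezes `cos(lat)` at the gyre centre (divergence-free
  exactness), particle *updates* use `cos(lat)` at the particle.
* Field sampling near coasts: `NA` (land) corners contribute zero to
  velocities (flow decays toward the coast) but are renormalized away for
  scalars, so a wet-cell particle always samples finite hydrography.
* Vertical reflection is mirror reflection iterated into `[0, bottom]`.
* Zero-variance contrast groups with unequal means yield `g = NA` with a
  warning rather than an infinity.
* Empty settlement sets propagate cleanly: empty footprint `(none)` at
  frequency 1, zero-row connectivity with the island list preserved.
* Isothermal profiles, self-intersecting zone rings, missing field
  variables, and fields shorter than the simulated duration are all
  explicit errors naming the offending object.

## Problem sizes in the test suite

The engine's correctness properties are scale-free, so the suite runs
them at deliberately small sizes: drift/settlement fixtures use tens of
particles over 10–60 days; the diffusive-variance check uses 1e5
single-step samples; the well-mixed check uses 1e4 particles in a 50 m
column; Kruskal–Wallis calibration uses 500 null datasets; the retention
experiment runs 10 iterations of 500 particles per gyre strength. The
full study configuration (100 iterations of 10,000 particles over 71
days) is what `run_simulation()` defaults express; nothing in the code
depends on the reduced sizes.

## Known limitations

* Advection is first-order; the Euler-vs-reference convergence test
  quantifies the error but a higher-order scheme is deliberately out of
  scope (the reference implementation is Forward Euler).
* Land detection is at grid-cell resolution; there is no sub-cell
  coastline, consistent with the onshore-mortality semantics.
* `kz` sampling uses the same multilinear interpolation as the other
  fields rather than a dedicated vertical spline; with the analytic
  (piecewise-smooth) diffusivity profiles used here the difference is
  immaterial, but it would matter for sharply structured observed
  diffusivities.
* Volitional swimming, feeding, predation and growth dynamics are
  unparameterized — unknown for the species, and excluded by design.
* The statistics treat larvae as independent across and within
  iterations; there is no correction for shared-iteration correlation.
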