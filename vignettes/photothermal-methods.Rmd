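---
title: "Methods: Monte Carlo photothermal therapy simulation with gold nanorods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo photothermal therapy simulation with gold nanorods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnrtherm)
```

## Problem and scope

Photothermal therapy kills tumor tissue by converting absorbed laser light
into heat. Gold nanorods (GNRs) injected into the tumor raise its
near-infrared absorption so a 1064 nm laser heats the tumor selectively.
The treatment goal is a window, not a maximum: tumor temperatures between
43 °C and 50 °C drive apoptosis (clean programmed cell death), while higher
temperatures cause necrosis and collateral damage in the surrounding skin.
`gnrtherm` simulates the whole chain — light transport, heat conduction,
dose scoring — and sweeps treatment conditions (laser power, nanorod
loading, heating/cooling duty cycle, total time) for the schedule that
maximizes time-in-window per unit of collateral hazard.

## Domain and materials

The skin model is a 30 × 30 × 10 mm block of four layers stacked from the
surface: epidermis (0.08 mm), papillary dermis (0.5 mm), reticular dermis
(0.6 mm) and subcutaneous fat (7.82 mm). The layer table (thickness, ρ,
c~p~, k, μ~a~, μ~s~, g) ships in `inst/extdata/skin_materials.yaml` and is
read by `skin_materials()`. The stated thicknesses sum to 9.0 mm in a 10 mm
deep domain; the remainder's material is not specified by the sources of
the layer table, so the subcutaneous fat is extended to the bottom of the
domain (the most plausible continuation, and the choice with the least
contrast in properties).

The tumor is a cylinder of 10 mm diameter and 3.5 mm length with its top
face 0.1 mm below the surface, coaxial with the beam. Its host optical
properties (μ~a~ = 0.08 mm⁻¹, μ~s~ = 1.28 mm⁻¹, g = 0.925) are modified by
the nanorod loading (below).

**Voxelization.** Materials are assigned by voxel center. The grid is
uniform in x and y; z slices are given by an edge vector. A 0.25 mm
isotropic voxel cannot represent the 0.08 mm epidermis, so by default
(`fine_surface = TRUE`) each of the three thin surface layers is subdivided
into equal slices of at most 0.04 mm so that every layer boundary falls on
a voxel face; below 1.18 mm the slices are ~`voxel` thick. The conduction
stencil supports dx ≠ dy ≠ dz, so anisotropic voxels are exact, not an
approximation. The coarse profile used for parameter sweeps
(`voxel = 0.5, fine_surface = FALSE`) drops the epidermis (its voxel
centers fall in the papillary dermis); this trades a 0.08 mm optical detail
for a ~50× faster thermal solve and is the documented sweep condition, not
a hidden approximation.

**Normal-tissue region of interest.** Collateral damage is scored over the
non-tumor voxels within half a tumor diameter (5 mm) of the tumor. The
boundary between "radial only" and "all directions" was genuinely open; the
package uses the Euclidean shell in all directions because conduction
spreads heat in all directions, so restricting the shell radially would
blind the metric to damage below the tumor. Distances are measured between
voxel centers (surface voxels of the tumor mask), which is within half a
voxel of the continuum definition and converges with the grid.

## Nanorod optics

A 67 × 10 nm rod (the geometry with peak absorption efficiency at 1064 nm)
is characterized by its equal-volume-sphere radius
r~eff~ = (3V/4π)^1/3^ ≈ 10.79 nm and efficiencies Q~a~, Q~s~. Loading at
volume fraction f~v~ adds μ~np~ = 0.75 f~v~ Q / r~eff~ to each coefficient
of the host tumor, additively (`mix_optical_properties()`); the anisotropy
g is left at the host value because the mixing rule is defined for μ~a~ and
μ~s~ only and the loaded-tissue tables list no g.

The efficiencies of the reference rod come from discrete-dipole
computations that are not reproduced here (out of scope). Instead, Q~a~ and
Q~s~ are **calibrated**: `calibrate_efficiency()` inverts the mixing model
against the published mixed-tissue coefficients at the anchor loading
f~v~ = 10⁻³ (118.419 and 6.101 mm⁻¹ over baselines 0.08 and 1.28 mm⁻¹),
giving Q~a~ ≈ 1.70. Because the model is linear in f~v~, this one-point
calibration reproduces the published columns at 10⁻⁴, 10⁻⁵ and 10⁻⁶ to
their printed 3 decimals (verified in the test suite and by
`scripts/acceptance.R`). The backed-out Q values are calibration constants
of this package, not reproductions of the original dipole computations —
they absorb, for example, any rounding of r~eff~ upstream.

## Photon transport

`run_monte_carlo()` implements the classic hop–drop–spin walk with photon
weights:

* **Launch**: uniform over a top-hat disc (default 10 mm, the tumor
  diameter) at the surface, normal incidence.
* **Hop**: a dimensionless optical depth −ln ξ is sampled once and consumed
  across voxels in proportion to the local μ~tot~, using exact ray–voxel
  traversal. Within any homogeneous region this reproduces
  S = −ln ξ / μ~tot~; across interfaces it is the unbiased generalization.
  Voxels with μ~tot~ = 0 (inert material) are crossed without consuming
  optical depth.
* **Drop**: ΔW = W μ~a~/μ~tot~ is tallied in the interaction voxel.
* **Spin**: deflection cosine from the Henyey–Greenstein inverse CDF with
  the material's g (the isotropic branch 2ξ−1 when g = 0), azimuth 2πξ,
  then a norm-preserving rotation of the direction vector with the standard
  special case when the direction is nearly parallel to z. The rotation
  used is the standard spherical form that preserves unit norm and the
  sampled deflection angle; published variants of these formulas differ in
  azimuth sign conventions (and occasionally contain typos), so the tests
  assert the two invariants — |u′| = 1 and u·u′ = cos θ — rather than one
  printed variant.
* **Termination**: Russian roulette below weight 10⁻⁴ with survival
  probability 1/10 (unbiased); photons crossing any domain face are tallied
  as escaped.

Interfaces are index-matched: no Fresnel reflection or refraction, because
no refractive indices are part of the model. This overestimates slightly
the light entering the skin relative to a mismatched-boundary model.

The RNG is a counter-seeded xoshiro256++; each photon's substream is
derived from (seed, photon index), so runs are bit-reproducible for a given
seed regardless of execution order. The deposited array is normalized per
launched photon; with the beam power P~l~ it becomes a volumetric source
without re-running transport, which the sweep exploits.

## Heat conduction

`run_treatment()` advances ρc~v~ ∂T/∂τ = q + ∇·(k∇T) with an explicit
finite-difference update: per voxel,
ΔT = Δτ/(ρc~v~V) · (q + Σ~faces~ G (T~nb~ − T)) with face conductance
G = k~harm~ A/d and k~harm~ = 2kk′/(k+k′), the harmonic mean that makes the
steady flux across a two-material interface exact. Choices:

* **Source normalization**: q~voxel~ = P~l~ × (deposited fraction), so the
  total injected power is P~l~ times the absorbed fraction. This makes the
  fluence-rate normalization of the continuum source term explicit.
* **Stability**: the update is a convex combination iff
  Δτ ≤ ρc~v~V / ΣG per voxel; `stability_timestep()` returns half that
  bound (safety 0.5) and `step_temperature()` refuses steps above the
  bound. The discrete maximum principle and exact adiabatic energy balance
  are tested properties, not assumptions.
* **Boundaries**: adiabatic by default — the conservative closure of the
  interior stencil and the one that makes energy accounting exact —
  with optional fixed-temperature far faces and an optional convective top
  surface (h, T~amb~). For the short treatments simulated here the choice
  of far boundary is immaterial (heating is localized within a few mm of
  the tumor); the test suite uses adiabatic closures precisely because they
  are exactly checkable.
* **Schedule**: heating phases of τ~h~ alternate with cooling phases of
  τ~c~; τ~tot~ is total elapsed time including cooling, and a final partial
  cycle is truncated at τ~tot~. Steps are clipped to phase switches and
  snapshot times, so both are hit exactly (variable steps below the bound
  are valid for an explicit scheme).
* **Initial temperature**: 37 °C for skin, 20 °C for phantom experiments.

Blood perfusion and metabolic heat are deliberately absent: the governing
equation modeled here is pure conduction with a laser source. Adding a
perfusion sink would lower late-time temperatures, so hazard values at long
treatment times are conservative (over-)estimates.

## Dose metrics

Per snapshot, `apoptosis_ratio()` is the tumor volume fraction with
43 < T < 50 °C — strict inequalities, matching the window's definition —
and `thermal_hazard()` is the volume-weighted mean hazard weight over the
ROI with the band table: weight 1 up to 43 °C, 2 on [43, 50), 3 on
[50, 70) (protein denaturation), then 4…8 through welding,
permeabilization, vaporization, carbonization and ablation. Bands above
43 °C are left-closed as printed in the source table; the table as printed
leaves exactly T = 300 unassigned, which this package resolves as weight 8
(T ≥ 300). Volumes are voxel counts × voxel volume (partial voxels
ignored; the per-slice voxel volumes of anisotropic grids are respected).

The starred retention metrics are trapezoidal time-averages of the
snapshot series divided by elapsed time (default snapshot interval 1 s;
2 s in the sweep profile — the integrands are piecewise-smooth and the
Cauchy test in the suite shows ≲10⁻³ sensitivity at these intervals), and
θ~A,eff~\* = θ~A~\*/θ~H,n~\* exactly.

## Condition sweep

`condition_grid()` defaults to the full study grid — τ~tot~ 120…960 s step
120, P~l~ 0…2000 mW step 50, f~v~ 10⁻³…10⁻⁶, τ~h~/τ~c~ ∈ {15, 20, 30, 60} s
(2688 conditions). `run_sweep()` shares work across conditions that cannot
differ: one transport run per f~v~ (absorption is independent of power and
schedule) and one unit-power thermal run per (f~v~, τ~h/c~, τ~tot~),
scaling the temperature rise by P~l~ — exact because the conduction update
is linear in the source. Rows are deterministic given the base seed
(per-f~v~ substreams), order-independent, and checkpointable to CSV.
`select_optimum()` takes the θ~A,eff~\*-argmax per treatment time, breaking
ties toward lower power, then shorter duty cycle — the cheaper and gentler
condition.

The default sweep profile (0.5 mm voxels, 10⁵ photons, 2 s snapshots) is
the package's desk-scale choice: it reproduces the qualitative structure of
the optimization — optimal P~l~ non-increasing in τ~tot~, θ~H,n~\*
non-decreasing in P~l~, lighter loadings yielding lower hazard — and the
broad magnitude of the optimal effective ratio (~0.5–0.7). Exact published
optimum values are not recoverable by any re-implementation, because the
original grid resolution, photon count and boundary conditions are
unstated; treat desk-scale absolute values as profile-dependent.

## Phantom preset

`build_phantom()` mirrors the validation experiment: a nanorod-loaded core
(10 mm diameter, 10 mm deep, f~v~ = 2×10⁻⁵) in a plain polyacrylamide
cylinder (40 mm diameter, 30 mm long; ρ = 1070 kg/m³, c~p~ = 3810 J/(kg K),
k = 0.56 W/(m K)), initial temperature 20 °C, with voxels outside the outer
cylinder inert. Two pieces of the physical experiment are not in the
published record and are therefore synthetic here, clearly so: the gel's
optical coefficients (defaults: water-dominated μ~a~ = 0.014 mm⁻¹, weak
scattering μ~s~ = 0.1 mm⁻¹ — a clear gel) and the exact radial thermocouple
offsets (`phantom_probe_locations()` defaults to 0/5/10/15 mm at 1 mm
depth). Consequently the phantom preset supports *methodological*
validation — probe extraction, `rmse()` comparison of simulated versus
measured traces supplied by the user as CSV — but no quantitative claim
against the original measured traces, which are not available.

## What the tests do and do not show

The suite verifies each stage against independent oracles at small scale:
closed-form and distributional checks for the samplers (10⁵ draws),
Beer–Lambert depth profiles in a pure absorber, exact weight conservation,
analytic two-voxel relaxation and tridiagonal steady states for the
conduction scheme, 10⁴-step maximum-principle sweeps, brute-force
recomputation of masks and dose metrics, and a reduced condition sweep
(2 treatment times × 7 powers × 2 duty cycles at the coarse profile,
~1 minute) for the optimization trends. Passing these shows the simulator
is a faithful implementation of the stated model; it does not validate the
model against living tissue — no perfusion, no temperature-dependent
properties, no phase change, no Arrhenius/CEM43 damage kinetics (the
band-weight hazard is a deliberate, coarser alternative), and no optical
boundary mismatch.
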