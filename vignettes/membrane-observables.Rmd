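---
title: "Synthetic bilayers with analytic ground truth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic bilayers with analytic ground truth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymem)
```

## Scope and model assumptions

`asymem` analyses planar, two-leaflet lipid bilayers. The membrane normal
is fixed to the z axis throughout — there is no normal fitting or
curvature handling, which is exact for the near-planar systems the package
targets and wrong for vesicles or strongly undulating membranes. All
depth-resolved observables assume a *recentred* trajectory
(`recenter_frames()`), which translates each frame so the lipid centre of
mass sits at z = 0.

Leaflets are assigned by the **sign of a reference atom's z coordinate**
(phosphate-level `headgroup_ref` for phospholipids, `hydroxyl_ref` for
sterols) rather than by clustering. For a planar, non-porated bilayer the
sign rule is exact; lipid flip-flop, if present, shows up as frame-to-frame
changes of the per-frame assignment and is reported separately
(`$flip_flop`) rather than silently averaged away.

Internal units are nm, ps, amu and elementary charges; pressures are
reported in bar (1 kJ mol⁻¹ nm⁻³ = 16.6054 bar, fixed in one place) and
potentials in mV.

## The synthetic generator: what it emulates, and what it does not

No public trajectory data accompany the membrane systems this package
models, and equilibrium all-atom ensembles can only be produced by an MD
engine. The generator therefore emulates the *ensemble statistics* that
the observables consume, with every controlled quantity recoverable in
closed form:

* **Headgroup density.** Reference atoms are drawn
  Normal(±`headgroup_peak_z`, `headgroup_sigma`) per frame, so the
  headgroup density profile has peaks at exactly ±d/2 and the ground-truth
  peak-to-peak thickness is `2 * headgroup_peak_z` (default 3.9 nm, a
  typical phospholipid bilayer).
* **Chain order.** For carbon i the analysis measures the angle of the
  C(i−1)→C(i+1) chord to the normal. The generator constructs chains from
  these chords directly (even- and odd-index carbons form interleaved
  sub-chains), placing each chord at the fixed polar angle θ\* with
  (3 cos²θ\* − 1)/2 equal to that carbon's target. Recovery is therefore
  *exact* — machine precision, not Monte-Carlo — which makes the recovery
  tests sharp even for non-constant per-carbon profiles. The azimuth is
  redrawn uniformly per chain per frame. The default target of 0.2 at
  every carbon sits in the middle of the liquid-ordered range.
* **Tilt.** The molecular axis (headgroup → midpoint of the terminal
  chain carbons; hydroxyl → last tail carbon for sterols) is pointed so
  its angle to the bilayer *plane* equals a per-molecule, per-frame draw
  around the prescribed mode (defaults 73° for phospholipids, 75° for
  CHOL, within the 71–78° range typical of ordered bilayers). The draw
  spread is 2.5°: narrow enough that the histogram mode estimator resolves
  the target to well under a degree at a few thousand samples, wide enough
  that the histogram is not degenerate.
* **Area fluctuation.** The box area follows a stationary AR(1) series
  (φ = 0.9) with prescribed SD, mimicking barostat wander without
  dynamics; x/y coordinates scale affinely with the box.
* **Waters and ions.** Waters are single interaction sites
  (`water_oxygen`) on continuous reflected AR(1) paths confined to
  |z| > `headgroup_peak_z` — permeation and density observables need only
  one site. One +1 counterion is added per −1 of lipid charge, so every
  generated system is exactly neutral when the charge sheets sum to zero.
* **Charges.** Ground-truth electrostatics are specified as sheets
  (z, σ): realised as 64 discrete point charges per sheet, they have the
  closed-form plate-capacitor potential, step = σd/ε₀ = 361.9 mV for
  σ = 0.01 e nm⁻², d = 2 nm.
* **Permeation.** `inject_permeation_events()` rewrites chosen waters'
  z-paths to cross the hydrophobic slab monotonically with an exact number
  of strictly-inside frames, giving events with known direction and dwell
  time.

What the generator does **not** emulate: force-field energetics, lipid
diffusion and chain dihedral dynamics, undulations, electrostatic
screening, or any correlation between observables (e.g. order–thickness
coupling). Passing recovery tests therefore demonstrates that the
*analysis* is correct, not that any particular force field or membrane
reproduces these numbers.

## Numerical choices

* **Density profiles** use uniform bins with an edge pinned at z = 0
  (default width 0.1 nm) and divide by the mean lateral area; the profile
  integral then equals the selected mass/charge exactly, which is enforced
  as a test invariant.
* **Thickness and tilt modes** refine the maximal bin by three-point
  parabolic interpolation, decoupling the estimate from bin placement. A
  monotone half-profile (no interior peak) is an error, not a guess.
* **Order parameters** use the hydrogen-free C(i−1)→C(i+1) chord as an
  approximation to the C–H deuterium convention (synthetic chains carry no
  hydrogens); the implementation is verified against a brute-force
  per-vector loop oracle to 1e−12.
* **Pressure profiles** distribute each pair virial along the straight
  minimum-image line between the particles (Irving–Kirkwood contour; the
  Harasima variant is out of scope), with segment–slab overlap fractions
  normalised to sum to exactly 1 so the slab decomposition reproduces the
  global virial to machine precision. The kinetic term is ρ(z)·kB·T with a
  supplied temperature — an equipartition substitute, since synthetic
  configurations carry no velocities. The module runs only on toy
  pair-interaction ensembles: reproducing all-atom pressure curves is an
  MD-engine task.
* **Surface tension** integrates (P_N − P_L) by the slab-sum (midpoint)
  rule, the exact quadrature for slab-averaged data: a 100 bar anisotropy
  over 1 nm gives 10 mN m⁻¹ identically.
* **Electrostatic potential** is the double cumulative trapezoid of the
  charge density from the lower box edge with ψ = 0 and dψ/dz = 0 there,
  relative permittivity 1 (explicit charges). No periodic dipole
  correction is applied: the reported quantity is a *region difference*
  (mean ψ over |z| > exterior bound minus mean over |z| < interior bound,
  positive when the exterior is higher), for which the correction cancels
  in mirror-symmetric setups. The conventional region bounds are 3 nm
  (interior) and 11 nm (exterior), overridable for smaller boxes.
* **Permeation detection** is a per-molecule finite-state machine:
  entering the open hydrophobic interval from side s and leaving through
  the opposite bound emits one event; leaving through the same bound
  resets silently. Crossings between consecutive frames are resolved by
  the minimum-image displacement, so paths that wrap through the periodic
  boundary outside the membrane never count. Dwell time counts frames
  *strictly inside* times the frame spacing, which makes injected events
  exactly recoverable. The hydrophobic slab is bounded where the
  tail-carbon mass density exceeds 50% of its maximum; above-threshold
  runs separated by less than 1.5 nm are merged (the midplane density dip
  of one bilayer), while genuinely separate membranes several nm apart
  yield two regions.
* **Apportionment** of compositions into integer counts uses the
  largest-remainder method with a deterministic tie-break (descending
  fraction, then lexical species name), so counts always sum exactly and
  per-species error is below one lipid.

## Open design decisions

* Whether the outer or inner leaflet absorbs the area-matching offset is
  model-specific; `area_match_offsets()` exposes it as
  `leaflet_to_adjust`.
* The frame spacing `dt` is always a required input, never inferred from
  file metadata.
* "Most probable" tilt angle is the histogram mode (refined); fitting a
  parametric distribution would be an alternative but adds model
  assumptions the histogram does not need.
* Ion valences are monovalent by default; the neutrality bookkeeping
  rejects configurations it cannot balance rather than silently rounding.
* Model-family labels (H00…H50, O33/I00/I10/I20, ±5%/−10%, D0/D2H/D2M/D2L/D5)
  are free-text labels on plans; exact per-model compositions are always
  user-supplied.

## Problem sizes

The test suite and the acceptance script run on deliberately small
systems, chosen as the smallest sizes at which every recovery tolerance is
comfortably met: bilayers of 60 lipids per leaflet (≈ 120 lipids total,
the scale of small published membrane models) with 200 frames for
ground-truth recovery; pair ensembles of 500 particles × 50 configurations
for the pressure identities; 100 seeded trials of up to 10 injected
crossings each for the permeation detector. Generation and analysis of a
200-frame bilayer takes about two seconds.

## Known limitations

Planar geometry only; no binary trajectory formats (XTC/DCD); no
three-body or long-range electrostatic virials in the pressure module; no
permeability-coefficient (counting → Pf) conversion; no domain/raft
clustering statistics. The generator's independence between observables
means cross-observable correlations in real membranes are untested by
construction.
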