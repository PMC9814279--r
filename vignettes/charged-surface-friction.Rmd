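---
title: "Linking surface charge heterogeneity to interfacial friction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking surface charge heterogeneity to interfacial friction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfriction)
```

## The problem

A sessile droplet's contact angle θ is the standard macroscopic proxy for
how strongly a solid surface grips water: by the wetting scaling
λ\* ∝ (1 + cos θ)², two surfaces with similar θ should have similar
solid–water friction coefficients λ. Surfaces decorated with small partial
charges (|q| ≤ 0.36 e, typical of 2D materials and biomolecular
backbones) break this expectation: the charges barely change θ or the
total interfacial energy, but they *corrugate* the microscopic energy
landscape that a first-layer water molecule experiences as it slides, and
friction responds to the corrugation, not to the mean attraction. The
quantitative statement is a linear relationship

λ = ζ · (ΔE_micro)²,  with (ΔE_micro)² = ⟨(E_micro − ⟨E_micro⟩)²⟩,

where E_micro is the water–surface interaction energy resolved on a fine
in-plane grid, and ζ ≈ 130 (in N s m⁻³ per (kJ/mol)², the unit convention
fixed by this package — the number is only comparable under it). Because
the Coulomb part of E_micro is linear in q, the corrugation variance —
and with it λ — grows as q², which is why a "small" charge has an
outsized effect on friction while leaving wetting almost untouched.

This package implements the full chain at desk scale: model surfaces,
energy maps and their fluctuation statistic, the Green–Kubo friction
estimator, contact-angle extraction from density fields, and the λ–(ΔE²)
model fit, with synthetic generators providing ground-truth inputs in
place of large-scale MD trajectories.

## Model surfaces

Three rigid, exactly neutral periodic lattices:

* **Honeycomb** (`build_hexagonal`): graphene-like sheet, bond length
  0.142 nm (26 × 16 unit cells reproduce a 6.395 × 6.816 nm footprint).
  The default `"para"` decoration places one +q and one −q atom per
  hexagon on para (diagonally opposite, 2 bond lengths apart) vertices, so
  charged sites form a periodic sublattice with equal ± counts; a sparser
  checkerboard-of-hexagons variant (`"para-sparse"`) is provided because
  the areal density of charged pairs is a genuinely open choice — it
  rescales (ΔE_micro)² at fixed q without changing any scaling law, so it
  is exposed as a parameter rather than hard-wired.
* **Square lattice** (`build_square`): lattice constant 0.25 nm, ±q
  checkerboard. Checkerboards only tile for even repeat counts; an
  untileable request is an error, never a silent charge imbalance.
* **Rigid CH₂ plane** (`build_ch2`): methylene groups (C–H 0.109 nm,
  H–C–H 109.5°, H pointing at the water) on a 0.25 nm square packing with
  q_C = −2 q_H, emulating a lipid-backbone surface; q_H spans 0 to
  0.36 e. The CH₂ Lennard-Jones parameters follow a standard all-atom
  alkane set (C: 0.276 kJ/mol, 0.35 nm; H: 0.1255 kJ/mol, 0.25 nm) and
  are configurable, as no single canonical choice exists for a rigid
  united plane.

Solid atoms default to ε_ss = 0.2325 kJ/mol, σ_ss = 0.34 nm. Neutrality
is enforced by integer bookkeeping of ± sites (the charge sum is exactly
zero in floating point, and validated). Coordinates put the heavy-atom
plane at z = 0 with water at z > 0; all lengths are nm, energies kJ/mol.

## Energy landscape

Water is the rigid three-site SPC/E model (LJ on oxygen only).
`pair_energy()` sums LJ (Lorentz–Berthelot combination by default;
geometric optional) and Coulomb terms over all water-site/surface-atom
pairs under the minimum-image convention, with independent cutoffs for
the two terms (both 1.0 nm by default). Electrostatics is a truncated
direct sum rather than an Ewald/PME treatment: this is a deliberate
desk-scale approximation, acceptable here because every surface is
exactly neutral (the leading truncated multipole vanishes) and because
all q-scaling conclusions rest on the linearity of the Coulomb term in q,
which truncation preserves exactly. Absolute energies near the cutoff
should not be over-interpreted.

The microscopic map E_micro lives on a grid of 0.25 Å² cells (0.05 nm
edge) tiling the periodic cell; an edge that does not tile the cell is an
error that reports the nearest commensurate choice. Two routes fill it:

* `accumulate_map()` bins every first-layer water observation from
  trajectory frames by its oxygen (x, y) — the first layer is the
  half-open slab (0, 0.50 nm] above the plane — and averages per cell.
  Binning by oxygen position, and averaging instantaneous observations
  rather than per-molecule time averages, are defaults where the
  convention is genuinely open; the alternative (`average = "molecule"`)
  is implemented.
* `probe_map()` is a deterministic stand-in: a rigid water at each cell
  centre, oxygen at `z_probe` (default 0.35 nm, near the oxygen–solid LJ
  minimum where first-layer oxygens concentrate), averaged over a fixed
  quasi-uniform quadrature of 32 orientations (Fibonacci-sphere bisector
  directions with golden-angle spins). Orientations are
  Boltzmann-weighted at 300 K by default; `weighting = "uniform"` takes
  the plain mean. The uniform option exists for a precise reason: with
  Boltzmann weights the weights themselves depend on q, so the Coulomb
  component of the map is no longer exactly linear in q. All exact q²
  assertions (cell-wise doubling, variance ratio 4, log–log exponent
  2.000) therefore use uniform weighting — the linear-response limit —
  while Boltzmann weighting is the physically natural default for
  emulating occupancy.

`map_stats()` reports ⟨E_micro⟩ and (ΔE_micro)² as the *population*
variance over occupied cells, unweighted by default (the statistic is the
standard deviation of the map itself); occupancy weighting is available.
Unvisited cells are masked, never zero-filled. The E_micro histogram uses
0.05 kJ/mol bins by default. `interface_energy_density()` gives the total
solid–water energy per unit area over *all* waters, the quantity that
stays nearly constant while friction explodes.

## Green–Kubo friction

`friction_coefficient()` implements
λ = 1/(A k_B T) ∫₀^t_c ⟨F(t)F(0)⟩ dt with the tangential surface force in
kJ mol⁻¹ nm⁻¹, time in ps and area in nm²; the fixed conversion
(≈ 1660.54, `gk_unit_factor()`) expresses λ in N s/m³ and is verified in
the tests against an explicit SI-unit computation. The ACF
(`autocorrelation()`) is mean-subtracted (an equilibrium force should
average to zero; any drift is removed and recorded) and uses the biased
1/N normalisation so the estimate is integrable; the FFT and direct
O(N²) estimators are algebraically identical and tested to 1e−10. The
integral is trapezoidal on the series' own time grid, cut off at
t_c = 1 ps by default — the interval over which the running integral has
plateaued for these interfaces — and the running integral is always
returned, with a simple plateau flag (last fifth of the running integral
within 5% of the final value). When two in-plane components are supplied,
λ is their average; the default is a single (x) component. The force-sign
convention is irrelevant: λ is quadratic in F.

## Contact angles

The extraction chain follows the standard density-profile method:
`density_field()` bins molecule positions cylindrically (0.1 nm radial ×
0.05 nm vertical bins) about the time-averaged in-plane centre of mass;
`extract_interface()` estimates the bulk density from interior bins (a
high-quantile density reference makes this robust to shot noise in the
small inner shells) and finds, in every z-row above a wall-exclusion
height of 0.8 nm, the radius where the density falls through 0.5 ρ_bulk,
by linear interpolation. Rows whose interior never reaches 80% of bulk
are dropped: near the droplet apex the profile no longer cuts through
bulk liquid and the isodensity radius degenerates. `fit_contact_angle()`
fits a circle — an algebraic Kasa fit refined by orthogonal-distance
least squares, since the algebraic fit alone is badly biased on short
noisy arcs — and reports the tangent angle at the contact plane,
measured through the liquid. All knobs (threshold fraction, exclusion
height, bin widths, contact height) are arguments.

`huang_relative_friction()` evaluates the wetting-based relative friction
(1 + cos θ_a)²/(1 + cos θ_b)². One documented tension: at the simulated
end-point angles (88° → 68°) this expression gives 1.764, while the
narrative accompanying those angles describes the change as "about 50%".
The function implements the scaling exactly as defined; the discrepancy
is reported, not reconciled.

## The friction–corrugation fit

`fit_zeta()` regresses λ on (ΔE_micro)², through the origin by default
(as corrugation vanishes, so does the Coulomb contribution to λ; an
intercept option absorbs any LJ floor), using only records with
ΔE_micro < 0.45 kJ/mol — above that the linear regime ends — and
reporting exclusions. Hexagonal and square lattices are fit jointly by
default, reflecting that the slope is lattice-insensitive.
`q_scaling_exponent()` estimates the log–log exponent of corrugation or
friction against q (records at q = 0 are skipped with a warning).

## Synthetic generators and what the tests do (and do not) show

Every generator is seeded and reproducible, and each has an analysis
counterpart whose closed-loop recovery is tested:

* `gen_ou_force()` — exact discrete Ornstein–Uhlenbeck update with
  autocovariance σ² e^(−t/τ), so the Green–Kubo integral has the closed
  form σ²τ(1 − e^(−t_c/τ))/(A k_B T). The acceptance conditions use
  σ² = 25 (kJ mol⁻¹ nm⁻¹)², τ = 1 ps, dt = τ/100, n = 10⁶ samples and
  two averaged components on the 43.6 nm² footprint at 300 K: a
  correlation time of order the integration window, with enough data
  that the estimator's statistical spread (≈1.6% s.d.) sits well inside
  the 5% closed-form tolerance.
* `gen_droplet()` — uniform sampling inside a spherical cap with a
  tanh-smoothed boundary (width 0.3 nm, a typical simulated liquid–vapor
  interfacial width); optional Gaussian positional noise of `noise * R`
  emulates density noise. The recovery tests use R = 6 nm so that the
  interface arc above the 0.8 nm wall exclusion is long enough for a
  stable circle fit even at 60°, with 2 × 10⁶ observations (the
  statistics of a ~900-molecule droplet sampled over a couple of
  thousand frames) for the noisy case and 5 × 10⁶ for the noiseless one.
* `gen_first_layer()` — Metropolis sampling of *single-molecule* rigid
  water poses in the first layer on the solid–water energy alone.
  Water–water interactions are deliberately omitted: this exercises layer
  selection, binning and the Boltzmann consistency of maps, **not** the
  absolute friction or hydration structure of real interfaces.
* `gen_lambda_dataset()` — λ_i = ζ·varE_i·(1 + ε_i) with Gaussian
  relative noise.

Passing these tests demonstrates that the estimators recover known truths
under the stated noise models. It does not demonstrate the paper-scale MD
results themselves: the headline magnitudes (λ from 1.2 × 10⁴ to
4.9 × 10⁵ N s/m³ across 0–0.36 e, θ from 88° to 68°, E from −56 to −68
kJ mol⁻¹ nm⁻², ζ ≈ 130 from simulation, the CH₂ factor of 4 and the
square-lattice factor of 1000) require tens-of-nanosecond trajectories of
thousands of waters and are outside desk scale. What carries over exactly
are the structural claims: neutrality, periodicity, the q² law of
Coulomb corrugation, the closed-form Green–Kubo arithmetic, the
contact-angle geometry, and the ratio arithmetic connecting the printed
coefficients (4.9 × 10⁵ / 1.2 × 10⁴ ≈ 41 versus the wetting-based 1.76).

## Numerical choices and degenerate inputs

* First layer: half-open interval (0, 0.50 nm] — the upper boundary is
  included (only a thickness is physically specified; an explicit
  convention avoids double counting between layers).
* Grid commensurability tolerance 1e−6 nm; incommensurate edges error
  with the nearest commensurate suggestion.
* Water–atom distances below 0.05 nm flag an overlap but still return an
  energy (maps should not silently lose pathological frames).
* ACF lag bounds and integration cutoffs are validated; a constant
  (non-decaying) ACF is flagged as non-convergent rather than silently
  integrated.
* Collinear interface points, fits that never reach the contact plane,
  and monotone (non-droplet) density profiles are explicit errors.
* `fit_zeta()` with every record above the corrugation cutoff, or with
  too few records for the requested model, is an error; one record is
  enough only for the through-origin fit.
* Pipeline configs reject unknown keys (all listed at once) and check
  referenced files before any stage runs; a failed stage skips its
  downstream stages with the cause recorded in the JSON report, and
  identical config + seed reproduce identical reports up to the
  timestamp.

## Known limitations

Truncated electrostatics instead of PME; rigid single-layer solids only;
no water–water interactions in the Monte Carlo generator; no
line-tension or droplet-size corrections to the contact angle; the
Green–Kubo estimator assumes a stationary force series and a plateaued
running integral — both diagnostics are reported, neither is enforced.
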