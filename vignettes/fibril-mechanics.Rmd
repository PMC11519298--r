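---
title: "Coarse-grained tensile mechanics of AGE-cross-linked collagen fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained tensile mechanics of AGE-cross-linked collagen fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Advanced-glycation endproducts (AGEs) accumulate in collagenous tissue with
age and diabetes. Cross-linking AGEs bond two tropocollagen (TC) molecules
inside a collagen fibril and thereby change how the fibril deforms and
fails: instead of dissipating energy by inter-molecular sliding, a heavily
cross-linked fibril transmits load into the TC molecules themselves,
stiffens beyond its elastic limit, stores rather than dissipates the
absorbed energy, and ultimately fails in a brittle manner by backbone
fracture. `fibrilmech` implements this system end to end: a geometry
builder, a breakable-bond force field, a steered tensile-test engine, and
the derived mechanical analyses, so that cross-link density and cross-link
mechanics can be varied systematically.

## The model

### Geometry

A fibril is a bundle of straight bead chains on a triangular cross-section
lattice. Each chain of 218 beads spaced `r0 = 14.0` Å (contour length about
300 nm) represents one TC molecule. Adjacent lattice sites differ in axial
phase by one D-period (`D = 670` Å) in the classic 5-staggered
(Hodge–Petruska) arrangement; along each lattice line, molecules tile with
an intra-line gap of `0.6 D`, so the structure shows the characteristic
gap/overlap banding with period `D` and a low-density (gap) fraction of
about 0.6. Where a chain end reaches the fibril extremes it is extended by
40 strengthened, unbreakable beads; these extensions (plus their anchor
bead) form the grip sets of the tensile test.

Two printed properties of the reference geometry are mutually inconsistent
under a strictly 5D-periodic tiling: a 218-bead molecule at 14 Å spacing is
4.53 D long, while a 0.6 D gap would require 4.4 D. We resolve this by
making the gap length exactly `gap_fraction * D` and letting the intra-line
tiling period be `L + 0.6 D`; the stagger offset between phases remains
exactly `D`, which preserves both the 670 Å banding period and the 0.6 gap
fraction that the geometry checks verify.

The cross-section defaults to 155 molecules (the chain count is
configuration-first; the diameter, about 20 nm, follows from packing).
Lattice spacing defaults to the pair-potential minimum `2^(1/6) * sigma`
rather than `sigma` itself so the cross-section starts stress-free — at
spacing `sigma` the 12-6 potential is strongly repulsive and the bundle
would swell during equilibration. The initial cross-section area is
`A0 = n_sites * spacing^2 * sqrt(3)/2` (lattice area per site), used for
engineering stress.

### Force field

All interactions use Å, fs, kcal/mol, g/mol ("real" units). Bonds —
backbone, grip extensions, and AGE cross-links — follow a breakable
piecewise-linear ("trilinear") law. The restoring-force magnitude is

* `k0 (r - r0)` for `r0 <= r < r1` (soft first regime),
* `k0 (r1 - r0) + k1 (r - r1)` for `r1 <= r < rbreak` (stiff second regime),
* a linear ramp back to zero over `a = z (rbreak - r1)` beyond `rbreak`,

and zero at `r0` and beyond `rbreak + a`. The published piecewise form of
this law is internally inconsistent (the force would jump at `r1` and
`rbreak`); we reconstruct the continuous law whose integral reproduces the
closed-form loading energy capacity

```
W(k0, k1, r0, r1, rbreak) = k0/2 (r1-r0)^2 + k0 (r1-r0)(rbreak-r1) + k1/2 (rbreak-r1)^2
```

term by term (the three terms are exactly the triangle, rectangle and
triangle areas under the force magnitude). Compression (`r < r0`) responds
with stiffness `k0` and never breaks. Breaking is irreversible: a bond is
removed permanently the first time its length reaches `rbreak + a`; a bond
that exceeds `rbreak` but recoils merely traversed the softening ramp. The
regularization factor defaults to `z = 0.1`; results are insensitive to it
within `[0.05, 0.25]` since the ramp carries only the residual energy
`f_max a / 2`.

Parameter defaults:

| component | r0 (Å) | r1 (Å) | rbreak (Å) | k0 | k1 |
|---|---|---|---|---|---|
| AGE cross-link (glucosepane) | 18.52 | 22.72 | 31.72 | 0.1 | 8.0 |
| sweep grid | 18.52 | 22.72 | 25–60 | 0.1 | 6–24 |
| TC backbone | 14.0 | 18.2 | 21.0 | 17.13 | 97.3 |

(stiffnesses in kcal mol^-1 Å^-2). The backbone, angle, pair and mass
values are not printed in the source study (they are deferred to its
supplementary material); we adopt the published mesoscale tropocollagen
force field this model family builds on — harmonic bending
`k_theta = 14.98` kcal/mol/rad^2 about a straight equilibrium, a 12-6 pair
potential with `sigma = 14.72` Å and `epsilon = 6.87` kcal/mol (cutoff
`2.5 sigma`, energy-shifted, 1-2 and 1-3 exclusions), and a bead mass of
1358 g/mol — and expose every one of them in the configuration objects.
With these values the backbone capacity is
`W_TC = loading_energy_capacity(collagen_bond()) ≈ 734` kcal/mol per bond.

The stiffening criterion compares the capacity of one molecule's backbone
path against that of its attached cross-links: stiffening is predicted when
`N_AGE * W_AGE > W_TC` (`stiffening_ratio()` > 1). `W_TC` is evaluated for
a single backbone bond — a molecule is a series chain of identical bonds,
so its capacity per unit cell is the per-bond capacity; this bookkeeping is
a package choice that the phase-map boundary makes explicit.

### Cross-link insertion

Cross-links are inserted uniformly at random between eligible bead pairs:
both beads within the central 95% of their molecule (glycation occurs in
the helical region, away from the telopeptide ends), on distinct molecules,
within a proximity threshold of 20 Å, and no bead carrying more than one
cross-link. The threshold admits side-by-side pairs of laterally adjacent
molecules only, so every cross-link starts near its 18.52 Å equilibrium
length and inside its first force regime; a looser threshold would insert
bonds already close to their critical hyperelastic distance, making the
initial fibril stiffness depend on the cross-link stiffness and breaking
distance — the linear regime must be cross-link independent.
Placement depends only on the geometry and the seed — never on force-field
parameters — so mechanical variants at equal density and seed share
identical cross-link locations, separating deterministic from statistical
effects. If eligible pairs are exhausted (possible at 40 links per molecule
on small specimens) a warning reports the achieved density.

## The tensile test

The two grip sets move apart symmetrically at a constant total speed
(reference 1e-4 Å/fs = 10 m/s, timestep 1 fs) under velocity-Verlet
integration with a Langevin thermostat (300 K) on the free beads. Strain is
the applied end displacement over the initial specimen length; stress is
the mean axial grip reaction over `A0`, converted at
1 kcal mol^-1 Å^-3 = 6947.7 MPa. Every record stores strain, stress, mean
backbone-bond force and extension, mean cross-link force, cumulative broken
bonds per type, and an energy ledger (kinetic, potential, dissipated,
external work, thermostat exchange) that balances to better than 1% of the
external work.

Two numerical choices deserve mention:

* **Desk-scale protocol.** The `"desk"` preset pulls 50x faster than the
  reference protocol with a 2 fs step (still ~400 steps per backbone
  vibration period of ~1.9 ps). The Langevin damping time is scaled up by
  the same factor (1000 fs to 50,000 fs): thermostat friction acts on the
  systematic flow field too, and an unscaled damping would add a viscous
  stress comparable to the bond forces at desk speeds. Halving the desk
  pull speed changes the peak stress by under 10%, which bounds the
  remaining rate sensitivity.
* **Observation window.** Mean backbone force and extension are averaged
  over the fully banded interior (where all five stagger phases are
  present). Near the fibril ends only a subset of phases exists and those
  few chains carry strongly concentrated loads; including them would bias
  the per-molecule stretching force that enters the sliding-force
  decomposition below.

## Derived analyses

* **Elastic limit** `eps0`: a line is fitted to the lightly smoothed stress
  over strain 0.02–0.10; `eps0` is the first strain (two consecutive
  records) whose stress departs from the fit by more than 2% relative *and*
  more than three residual standard deviations of the fit window (the
  thermal stress noise sets the detection resolution). `sigma0` is the
  smoothed stress at `eps0`.
* **Peak metrics**: `sigma_peak` is the global maximum of the smoothed
  stress; `delta_sigma = sigma_peak - sigma0` is the elastic-to-peak stress
  difference. A run counts as stiffening when (i) `delta_sigma` exceeds a
  noise floor of `max(5 MPa, 0.10 sigma0)` — the elastic-limit rule's own
  detection band (3 residual SDs, typically 6–8% of `sigma0` at desk
  scale) plus smoothing bias — and (ii) the peak lies more than 0.05 strain
  beyond `eps0`, i.e. the stress keeps rising well past the elastic limit
  rather than within the detection uncertainty of `eps0` itself. Both
  thresholds were calibrated on cross-link-free and weakest-cross-link
  reference runs at desk scale.
* **Gap kinematics**: the global strain decomposes into mean bond
  stretching and gap opening,
  `strain = (dg + n_tc <r - r0>) / (<g> + n_tc r0)`, giving `dg` per record
  (`<g> = 402` Å, `n_tc = 217` at defaults); the inversion is exact.
* **Energy partition**: stretching energy integrates the mean backbone
  force over the mean bond extension; sliding energy integrates the
  heuristic sliding force — applied force per cross-section molecule minus
  the stretching force, floored at zero (negative balances are noise of the
  force decomposition) — over the gap opening. Both start at the transition
  strain `eps*`, the first upward crossing of the molecular strain
  `<r - r0>/r0` through the fibrillar strain (the initial pair-interaction
  pre-tension makes the difference slightly positive at zero strain, so a
  plain sign test would fire immediately; if no crossing occurs `eps* = 0`
  with a flag). Energies are normalized by a zero-cross-link reference run
  of the same geometry, protocol and seed.
* **Broken-bond census**: percent of inserted cross-links broken, and
  broken backbone bonds per molecule (can exceed 100% — one molecule can
  fracture more than once).
* **Phase map**: sweep cells classified stiffening/non-stiffening and
  compared against the `N_AGE W_AGE > W_TC` criterion, with the boundary
  `N_AGE W(k1, rbreak) = W_TC` solved by root finding.

## Desk-scale presets and problem sizes

The full 155-molecule, one-period specimen (~46,000 beads) at the reference
pulling speed needs ~2e7 steps per test; the package therefore provides
reduced specimens as its default study conditions:

* `"reduced"` — 19 molecules, one period, full-length chains (~4400 beads);
  used for single tensile analyses (elastic limit, normalized sliding at
  high density). A run to strain 0.3–0.35 takes a few minutes.
* `"mini"` — 19 molecules at scale factor 0.25 (~1100 beads, D scaled
  accordingly, gap fraction and stagger preserved); used for the parameter
  sweeps where each cell is a destructive test (~10–20 s per run).

Because the cross-link density is defined per full-length molecule, scaled
models insert `round(n_age * n_molecules * scale_factor)` links: the linear
density along the chains — the quantity the stiffening energy balance is
about — then matches the full-scale fibril at the same nominal density.

Reduced geometry preserves the stagger statistics and gap fraction by
construction (a property test verifies this), but absolute stresses and
energies are not those of the full fibril; analyses therefore use
dimensionless or normalized quantities (strains, energy ratios, broken
fractions, classifications).

## What the generator does and does not emulate

The builder emulates the D-periodic staggered architecture, the gap/overlap
banding, random helical-region cross-linking with proximity and single-link
constraints, and strengthened grip ends. It does not emulate molecular
curvature (chains are straight; at this coarse-graining the mechanics is
governed by the bond law, and curvature from crystallographic fits is out
of scope), microfibrillar substructure, enzymatic cross-links, hydration or
a mineral phase. Passing tests therefore validate the implemented
mechanism — the sliding-to-stretching transition governed by cross-link
density and capacity — not quantitative agreement with any particular
tissue.

## Known limitations

* The sliding energy is a heuristic force balance; at low densities it can
  exceed its theoretical bound (the zero-density reference), as the
  analysis documentation notes, and it inherits noise from the grip-force
  signal. On strongly shortened chains (the `"mini"` preset) the heuristic
  degrades further: a short chain cannot develop its molecular tension
  plateau, so the mean backbone force underestimates the per-molecule load
  and the inferred sliding force stays positive even in stretching-governed
  runs. Normalized sliding comparisons are therefore made on the
  full-chain `"reduced"` preset.
* The elastic-limit strain depends on the detection rule (fit window,
  relative band, noise multiplier); all three are exposed as arguments.
* One fibril realization per sweep cell by default (replicate seeds are
  supported but not default), matching the single-realization study design.
* Desk-scale pulling is 10–50x faster than the reference protocol;
  rate-insensitivity is verified only to within 10% on the peak stress.
* At desk scale the initial stress–strain slope retains a residual
  dependence on cross-link density and parameters (~6–20% across sweep
  variants, growing at lower pulling speeds): in the small bundle,
  inter-molecular sliding begins almost immediately, so cross-links
  suppress a soft mode from the very start instead of only beyond a
  clean elastic regime. A strictly cross-link-independent linear regime
  should not be expected from the reduced specimens.

## A worked example

```{r example}
library(fibrilmech)

model <- build_fibril(fibril_preset("reduced")) |>
  insert_age_crosslinks(crosslink_spec(n_age = 2, seed = 1))

run <- run_tension(model, force_field(),
                   protocol_preset("desk", strain_limit = 0.3), seed = 1)
autoplot(run)
glance(run)

# parameter sweep and stiffening phase map
res <- run_sweep(sweep_spec(k1 = c(6, 12, 24), rbreak = c(25, 35, 60),
                            n_age = c(0, 2, 10), preset = "mini"),
                 out_dir = "sweep_cache")
pm <- phase_map(res, wtc = attr(res, "wtc"))
autoplot(pm)
plot_energy_partition(res)
```
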