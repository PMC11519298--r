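# fibrilmech

Coarse-grained tensile mechanics of collagen fibrils cross-linked by
advanced-glycation endproducts (AGEs).

Collagen type I fibrils are 5-staggered bundles of ~300 nm tropocollagen
(TC) molecules with a D = 67 nm gap/overlap banding. With age and diabetes,
sugar-derived AGE cross-links accumulate between molecules and change how
the fibril deforms: instead of dissipating energy through inter-molecular
sliding, a cross-linked fibril transmits load into the molecules, stiffens
beyond its elastic limit, and fails in a brittle way by backbone fracture.
`fibrilmech` is for researchers in fibril/tissue biomechanics who want to
explore that transition computationally: it builds the staggered bead-chain
geometry, inserts breakable cross-links of configurable stiffness,
strength and density, runs destructive constant-velocity (steered) tensile
tests with a compiled velocity-Verlet engine, and computes the derived
mechanical observables.

## The model in brief

Every bond (TC backbone, grip extension, AGE cross-link) follows a
breakable trilinear law with restoring-force magnitude

```
|F|(r) = k0 (r - r0)                      r0 <= r < r1
       = k0 (r1 - r0) + k1 (r - r1)       r1 <= r < rbreak
       = |F|(rbreak) (1 - (r - rbreak)/a) rbreak <= r < rbreak + a,  a = z (rbreak - r1)
```

whose integral up to `rbreak` is the bond's *loading energy capacity*

```
W = k0/2 (r1 - r0)^2 + k0 (r1 - r0)(rbreak - r1) + k1/2 (rbreak - r1)^2 .
```

A bond is removed permanently once it reaches `rbreak + a`. Glucosepane,
the reference cross-link, has `r0 = 18.52` Å, `r1 = 22.72` Å,
`rbreak = 31.72` Å, `k0 = 0.1`, `k1 = 8.0` kcal mol⁻¹ Å⁻²
(`W = 328.7` kcal/mol). Fibrillar stiffening is predicted by the energy
balance `N_AGE · W_AGE > W_TC` between a molecule's cross-links and its
backbone capacity; the level set at equality is the phase-map boundary.
Analyses include the elastic limit ε₀, the elastic-to-peak stress
difference Δσ = σ_peak − σ(ε₀), the sliding/stretching energy partition
(E_slide, E_stretch, normalized by a cross-link-free reference run) and
broken-bond censuses. See the methods vignette
(`vignettes/fibril-mechanics.Rmd`) for the full model description.

## Worked example

```r
library(fibrilmech)

# 19-molecule desk-scale fibril, glucosepane cross-links at 10 per molecule
model <- build_fibril(fibril_preset("mini")) |>
  insert_age_crosslinks(crosslink_spec(n_age = 10, seed = 1))

run <- run_tension(model, force_field(),
                   protocol_preset("desk", strain_limit = 0.35), seed = 1)
run
#> <tension_run> 238 records to strain 0.350; peak stress 769.5 MPa
#>   broken: 8 AGE, 0 backbone bonds

m <- glance(run)   # = fibril_metrics(run)
round(m$eps0, 3); round(m$delta_sigma, 1)
#> [1] 0.173
#> [1] 379.8
```

The fibril leaves its linear elastic regime near strain 0.17 and — at this
density of cross-links — keeps hardening to a peak far above the
elastic-limit stress (Δσ ≈ 380 MPa): the stiffening regime, driven by load
transfer from sliding to molecular stretching. With `n_age = 0` the same
specimen peaks just past its elastic limit and then softens by sliding.
`autoplot(run)` draws the stress–strain curve; `run_sweep()` +
`phase_map()` + `autoplot()` reproduce the (k1, rbreak, N_AGE) stiffening
maps, and `plot_energy_partition()` the sliding-to-stretching exchange.

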