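# shared fixtures; expensive simulation results are memoized so several test
# files can reuse one run

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# two beads joined by one bond, no pair interactions
mk_dimer <- function(stretch = 0.5, bond_type = "backbone", r0 = 14,
                     grip_both = FALSE) {
  particles <- tibble::tibble(id = 1:2, chain = c(1L, 1L), seq = 1:2,
                              kind = "body", x = 0, y = 0,
                              z = c(0, r0 + stretch))
  if (bond_type == "age") particles$chain <- 1:2
  structure(list(
    particles = particles,
    bonds = tibble::tibble(i = 1L, j = 2L, type = bond_type),
    chains = tibble::tibble(chain = unique(particles$chain)),
    grips = if (grip_both) list(left = 1L, right = 2L)
            else list(left = integer(0), right = integer(0)),
    config = fibril_config(n_chains = 2, n_particles_per_chain = 2),
    a0 = 100, g_mean = 0, n_sites = 2, n_molecules = 2,
    n_body_bonds_per_chain = 1L, l0 = r0 + stretch,
    n_age_target = 0L, n_age_inserted = 0L), class = "fibril_model")
}

# pairless force field (bonded interactions only)
ff_bonded <- function(...) {
  force_field(nonbonded = nonbonded_params(epsilon = 0), ...)
}

# small two-chain fibril for integrator health checks
mk_two_chain <- function() {
  build_fibril(fibril_config(n_chains = 2, n_particles_per_chain = 12,
                             end_extension_particles = 3, n_periods = 1,
                             d_period = 60, gap_fraction = 0.5))
}

# small fibril for inexpensive full tensile tests
mk_small_fibril <- function() {
  fixture("small_fibril",
          build_fibril(fibril_config(n_chains = 7, scale_factor = 0.15,
                                     n_periods = 1)))
}

# Table 1 parameter grid: 8 breaking distances x 5 stiffnesses + glucosepane
table1_grid <- function() {
  g <- expand.grid(k1 = c(6, 8, 12, 16, 24),
                   rbreak = c(25, 27, 30, 33, 35, 40, 50, 60))
  rbind(g, data.frame(k1 = 8, rbreak = 31.72))
}

# independent energy oracle: trapezoid integration of the force magnitude
integrate_bond_force <- function(p, r_to, dr = 1e-4) {
  r <- seq(p$r0, r_to, by = dr)
  f <- -bond_force(p, r)  # restoring magnitude for r > r0
  sum((f[-1] + f[-length(f)]) / 2 * diff(r))
}

# memoized desk-scale sweep: 3 x 3 grid at densities 0, 2, 10
mini_sweep <- function() {
  fixture("mini_sweep", {
    spec <- sweep_spec(k1 = c(6, 12, 24), rbreak = c(25, 35, 60),
                       n_age = c(0, 2, 10), preset = "mini", seeds = 1L,
                       include_glucosepane = FALSE)
    suppressWarnings(run_sweep(spec, quiet = TRUE))
  })
}

# memoized reduced-preset pair at density 10 and 0 (the full-chain
# specimens on which the sliding-force decomposition is meaningful)
reduced_pair <- function() {
  fixture("reduced_pair", {
    m <- build_fibril(fibril_preset("reduced"))
    proto <- protocol_preset("desk", strain_limit = 0.35)
    m10 <- insert_age_crosslinks(m, crosslink_spec(10, seed = 1))
    list(run10 = run_tension(m10, force_field(), proto, seed = 1),
         run0 = run_tension(m, force_field(), proto, seed = 1))
  })
}

# memoized reduced-preset tensile test: glucosepane cross-links at 2 per
# molecule, pulled to strain 0.3
reduced_glu_run <- function() {
  fixture("reduced_glu_run", {
    m <- build_fibril(fibril_preset("reduced"))
    m2 <- insert_age_crosslinks(m, crosslink_spec(2, seed = 1))
    run_tension(m2, force_field(),
                protocol_preset("desk", strain_limit = 0.3), seed = 1)
  })
}
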