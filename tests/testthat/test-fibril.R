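test_that("minimal two-chain build has the expected counts and topology", {
  cfg <- fibril_config(n_chains = 2, n_particles_per_chain = 10,
                       end_extension_particles = 2, n_periods = 1,
                       d_period = 20, gap_fraction = 0.5)
  m <- build_fibril(cfg)
  # small stagger: both chains extended on both sides -> 2 * (10 + 2*ext)
  expect_equal(nrow(m$particles), 2 * (10 + 2 * 2))
  # backbone bonds: per chain (n_total - 1), split into body and end types
  expect_equal(nrow(m$bonds), 2 * (14 - 1))
  expect_equal(sum(m$bonds$type == "backbone"), 2 * 9)
  per_bond_chains <- cbind(m$particles$chain[m$bonds$i],
                           m$particles$chain[m$bonds$j])
  expect_true(all(per_bond_chains[, 1] == per_bond_chains[, 2]))
  expect_true(length(m$grips$left) > 0 && length(m$grips$right) > 0)
  expect_length(intersect(m$grips$left, m$grips$right), 0)
})

test_that("default geometry shows the D-periodic banding and gap fraction", {
  m <- fixture("geom19", build_fibril(fibril_config(n_chains = 19)))
  expect_equal(axial_density_period(m), 670, tolerance = 0.02)
  gf <- gap_fraction_measured(m)
  expect_gt(gf, 0.55)
  expect_lt(gf, 0.65)
})

test_that("reduced-scale builds preserve stagger structure and gap fraction", {
  m <- build_fibril(fibril_config(n_chains = 19, scale_factor = 0.5))
  expect_equal(axial_density_period(m), m$config$d_period, tolerance = 0.05)
  gf <- gap_fraction_measured(m)
  expect_gt(gf, 0.55)
  expect_lt(gf, 0.65)
  phases <- table(m$chains$phase)
  expect_equal(length(phases), 5L)
})

test_that("degenerate and invalid configurations error", {
  expect_error(build_fibril(fibril_config(n_chains = 2, diameter = 10)),
               "diameter too small")
  expect_error(fibril_config(n_chains = 1), "at least 2")
  m1 <- build_fibril(fibril_config(n_chains = 2, n_particles_per_chain = 8,
                                   n_periods = 1, d_period = 30))
  m1$n_sites <- 1
  expect_error(axial_density_period(m1), "single-chain")
})

test_that("two-phase fixture has banding period equal to the stagger offset", {
  cfg <- fibril_config(n_chains = 2, n_particles_per_chain = 10,
                       end_extension_particles = 0, n_periods = 3,
                       d_period = 42, gap_fraction = 0.5)
  m <- build_fibril(cfg)
  expect_equal(axial_density_period(m, bin = 1), 42, tolerance = 0.1)
})

test_that("cross-link insertion hits the target density and all constraints", {
  m <- fixture("reduced_model", build_fibril(fibril_preset("reduced")))
  spec <- crosslink_spec(2, seed = 42)
  mx <- insert_age_crosslinks(m, spec)
  age <- mx$bonds[mx$bonds$type == "age", ]
  expect_equal(nrow(age), round(2 * m$n_molecules))
  expect_equal(mx$n_age_inserted, mx$n_age_target)
  # inter-chain only
  expect_true(all(mx$particles$chain[age$i] != mx$particles$chain[age$j]))
  # within the proximity threshold
  d <- sqrt((mx$particles$x[age$i] - mx$particles$x[age$j])^2 +
            (mx$particles$y[age$i] - mx$particles$y[age$j])^2 +
            (mx$particles$z[age$i] - mx$particles$z[age$j])^2)
  expect_true(all(d <= spec$proximity_threshold))
  # at most one cross-link per bead
  expect_false(any(duplicated(c(age$i, age$j))))
  # central 95% of the body beads only
  np <- m$config$n_particles_per_chain
  margin <- floor(np * 0.025)
  body_pos <- function(ids) {
    p <- mx$particles
    vapply(ids, function(id) {
      ch <- p$chain[id]
      sum(p$kind == "body" & p$chain == ch & p$id <= id)
    }, 0L)
  }
  pos <- body_pos(c(age$i, age$j))
  expect_true(all(pos > margin & pos <= np - margin))
})

test_that("insertion is deterministic in the seed and model-independent of bond parameters", {
  m <- fixture("reduced_model", build_fibril(fibril_preset("reduced")))
  a <- insert_age_crosslinks(m, crosslink_spec(2, seed = 42))
  b <- insert_age_crosslinks(m, crosslink_spec(2, seed = 42))
  c2 <- insert_age_crosslinks(m, crosslink_spec(2, seed = 43))
  expect_identical(a$bonds, b$bonds)
  expect_false(identical(a$bonds, c2$bonds))
  # n_age = 0 leaves the model unchanged
  m0 <- insert_age_crosslinks(m, crosslink_spec(0, seed = 1))
  expect_identical(m0$bonds, m$bonds)
})

test_that("exhausted eligible pairs warn and report the achieved density", {
  m <- build_fibril(fibril_config(n_chains = 4, scale_factor = 0.15,
                                  n_periods = 1))
  expect_warning(mx <- insert_age_crosslinks(m, crosslink_spec(150, seed = 1)),
                 "achieved density")
  expect_lt(mx$n_age_inserted, mx$n_age_target)
  expect_gt(mx$n_age_inserted, 0)
})
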