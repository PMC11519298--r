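test_that("trilinear bond force matches hand values and vanishes where it must", {
  glu <- glucosepane_bond()
  # equilibrium and post-failure
  expect_equal(bond_force(glu, 18.52), 0)
  expect_equal(bond_force(glu, glu$rbreak + glu$a), 0)
  expect_equal(bond_force(glu, 100), 0)
  # magnitudes at the regime boundaries: k0*(r1-r0), then + k1*(rbreak-r1)
  expect_equal(abs(bond_force(glu, 22.72)), 0.42, tolerance = 1e-12)
  expect_equal(abs(bond_force(glu, 31.72 - 1e-12)), 72.42, tolerance = 1e-6)
  # restoring signs: attractive beyond r0, repulsive below
  expect_lt(bond_force(glu, 20), 0)
  expect_gt(bond_force(glu, 17), 0)
})

test_that("bond force is continuous across all regime boundaries", {
  for (p in list(glucosepane_bond(), collagen_bond(), age_bond(24, 60))) {
    r <- seq(p$r0 * 0.5, p$rbreak + p$a + 2, length.out = 40001)
    f <- bond_force(p, r)
    # steepest branch is the post-break unloading ramp, slope fmax / a
    fmax <- p$k0 * (p$r1 - p$r0) + p$k1 * (p$rbreak - p$r1)
    s_max <- max(p$k0, p$k1, fmax / p$a)
    expect_lt(max(abs(diff(f))), s_max * diff(r[1:2]) * 1.5 + 1e-8)
  }
})

test_that("bond energy equals the integral of the force (finite differences)", {
  set.seed(7)
  for (p in list(glucosepane_bond(), collagen_bond(), age_bond(6, 25),
                 age_bond(24, 60))) {
    r <- runif(1000, p$r0 * 0.8, p$rbreak + p$a * 0.99)
    # keep clear of the kinks where the derivative is one-sided
    kinks <- c(p$r0, p$r1, p$rbreak, p$rbreak + p$a)
    r <- r[vapply(r, function(x) min(abs(x - kinks)) > 1e-3, TRUE)]
    h <- 1e-5
    dnum <- -(bond_energy(p, r + h) - bond_energy(p, r - h)) / (2 * h)
    expect_equal(dnum, bond_force(p, r), tolerance = 1e-4)
  }
})

test_that("loading energy capacity reproduces the closed form on the full grid", {
  # glucosepane reference: independent numeric integration oracle
  glu <- glucosepane_bond()
  expect_equal(loading_energy_capacity(glu), 328.662, tolerance = 1e-9)
  expect_equal(bond_energy(glu, glu$rbreak), 328.662, tolerance = 1e-9)
  expect_equal(integrate_bond_force(glu, glu$rbreak), 328.662,
               tolerance = 1e-5)
  # weakest and strongest sweep corners against the same oracle
  weak <- age_bond(6, 25)
  expect_equal(loading_energy_capacity(weak), 17.4348, tolerance = 1e-6)
  expect_equal(integrate_bond_force(weak, weak$rbreak),
               loading_energy_capacity(weak), tolerance = 1e-4)
  strong <- age_bond(24, 60)
  expect_equal(loading_energy_capacity(strong),
               integrate_bond_force(strong, strong$rbreak, dr = 5e-4),
               tolerance = 1e-5)
  expect_equal(loading_energy_capacity(strong), 16694.4, tolerance = 1e-4)
  # first-triangle-only limit (k1 -> 0, rbreak -> r1): only k0/2 (r1-r0)^2
  lim <- trilinear_bond(18.52, 22.72, 22.72 + 1e-9, k0 = 0.1, k1 = 1e-9)
  expect_equal(loading_energy_capacity(lim), 0.882, tolerance = 1e-6)
})

test_that("bond energy at rbreak equals capacity across Table 1 grid", {
  g <- table1_grid()
  for (i in seq_len(nrow(g))) {
    p <- age_bond(g$k1[i], g$rbreak[i])
    expect_equal(bond_energy(p, p$rbreak), loading_energy_capacity(p),
                 tolerance = 1e-6)
  }
})

test_that("capacity is strictly monotone in rbreak and k1", {
  k1s <- c(6, 8, 12, 16, 24)
  rbs <- c(25, 27, 30, 33, 35, 40, 50, 60)
  w <- outer(k1s, rbs, Vectorize(function(k, r)
    loading_energy_capacity(age_bond(k, r))))
  expect_true(all(apply(w, 1, diff) > 0))  # in rbreak
  expect_true(all(apply(w, 2, diff) > 0))  # in k1
})

test_that("stiffening ratio implements the energy-balance criterion", {
  expect_equal(stiffening_ratio(1000, 0, 500), 0)
  expect_equal(stiffening_ratio(1000, 2, 500), 1)
  wtc <- loading_energy_capacity(collagen_bond())
  r <- stiffening_ratio(wtc, 2, loading_energy_capacity(glucosepane_bond()))
  expect_equal(r, 2 * 328.662 / wtc)
  expect_error(stiffening_ratio(0, 2, 1), "wtc")
  expect_error(stiffening_ratio(10, -1, 1), "n_age")
})

test_that("parameter validation rejects ill-ordered or non-positive inputs", {
  expect_error(trilinear_bond(20, 18, 30, 1, 1), "r0 < r1")
  expect_error(trilinear_bond(10, 18, 15, 1, 1), "r0 < r1")
  expect_error(trilinear_bond(10, 18, 30, -1, 1), "k0")
  expect_error(trilinear_bond(10, 18, 30, 1, 1, z = 0), "k0 > 0")
  expect_error(force_field(end_bond = collagen_bond()), "unbreakable")
})

test_that("pair potential force vanishes at minimum and cutoff; matches energy slope", {
  p <- nonbonded_params()
  rmin <- 2^(1 / 6) * p$sigma
  expect_equal(pair_force(p, rmin), 0, tolerance = 1e-12)
  expect_equal(pair_force(p, p$cutoff + 1), 0)
  expect_equal(pair_energy(p, p$cutoff - 1e-9), 0, tolerance = 1e-6)
  r <- c(14, 16, 20, 30)
  h <- 1e-6
  dnum <- -(pair_energy(p, r + h) - pair_energy(p, r - h)) / (2 * h)
  expect_equal(dnum, pair_force(p, r), tolerance = 1e-5)
  expect_gt(pair_force(p, 13), 0)   # repulsive core
  expect_lt(pair_force(p, 20), 0)   # attractive tail
})

test_that("angle torque vanishes at equilibrium and matches energy slope", {
  a <- angle_params()
  expect_equal(angle_torque(a, pi), 0)
  th <- c(2.5, 3)
  h <- 1e-7
  dnum <- -(angle_energy(a, th + h) - angle_energy(a, th - h)) / (2 * h)
  expect_equal(dnum, angle_torque(a, th), tolerance = 1e-6)
})
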