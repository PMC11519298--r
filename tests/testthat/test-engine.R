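test_that("harmonic dimer oscillates at the analytic period", {
  d <- mk_dimer(0.5)
  run <- step_nve(d, ff_bonded(), n_steps = 20000, dt = 1,
                  record_interval = 5)
  ext <- run$series$ext_backbone
  zc <- which(diff(sign(ext)) > 0)
  period <- mean(diff(run$series$step[zc]))
  k <- collagen_bond()$k0
  analytic <- 2 * pi * sqrt(1358 / (2 * k * 4.184e-4))
  expect_equal(period, analytic, tolerance = 0.01)
})

test_that("NVE energy drift over 1e4 steps is below 1e-4 on the two-chain fixture", {
  m <- mk_two_chain()
  set.seed(11)
  v0 <- matrix(rnorm(3 * nrow(m$particles), sd = 3e-4), ncol = 3)
  run <- step_nve(m, force_field(), n_steps = 10000, dt = 1,
                  record_interval = 200, v0 = v0)
  etot <- run$series$e_kin + run$series$e_pot
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 1e-4)
})

test_that("zero-velocity equilibrium start stays static; zero pull leaves stress at zero", {
  d <- mk_dimer(0)
  run <- step_nve(d, ff_bonded(), n_steps = 1000, dt = 1)
  expect_equal(max(abs(run$series$ext_backbone)), 0)
  m <- mk_two_chain()
  proto <- tension_protocol(pull_speed = 0, dt = 1, temperature = 0,
                            damping = 2000, record_interval = 200,
                            equil_steps = 0, n_steps = 3000)
  run2 <- run_tension(m, force_field(), proto, seed = 1)
  expect_lt(max(abs(run2$series$fgrip)), 2)
  expect_equal(nrow(run2$breaks), 0L)
  expect_true(all(run2$series$strain == 0))
})

test_that("pulling a single cross-link to failure recovers its peak force and capacity", {
  pair <- mk_dimer(0, bond_type = "age", r0 = 18.52, grip_both = TRUE)
  pair$l0 <- 18.52
  glu <- glucosepane_bond()
  proto <- tension_protocol(pull_speed = 2e-3, dt = 1, temperature = 0,
                            damping = 0, record_interval = 5,
                            strain_limit = (glu$rbreak + glu$a + 1 - glu$r0) / 18.52,
                            equil_steps = 0)
  run <- run_tension(pair, ff_bonded(), proto, seed = 1)
  s <- run$series
  fmax_expect <- glu$k0 * (glu$r1 - glu$r0) + glu$k1 * (glu$rbreak - glu$r1)
  expect_equal(max(s$f_age), fmax_expect, tolerance = 0.01)
  i_pk <- which.max(s$f_age)
  work <- sum(diff(s$ext_age[1:i_pk]) *
              (head(s$f_age[1:i_pk], -1) + tail(s$f_age[1:i_pk], -1)) / 2)
  expect_equal(work, loading_energy_capacity(glu), tolerance = 0.01)
  expect_equal(tail(s$broken_age, 1), 1L)
  expect_equal(run$breaks$type, "age")
})

test_that("energy ledger balances external work within 1%", {
  m <- mk_small_fibril()
  mx <- insert_age_crosslinks(m, crosslink_spec(2, seed = 5))
  proto <- protocol_preset("quasistatic", pull_speed = 2.5e-3, dt = 1,
                           strain_limit = 0.25, record_interval = 200,
                           equil_steps = 1000)
  run <- run_tension(mx, force_field(age_bond = age_bond(6, 25)), proto,
                     seed = 2)
  s <- run$series
  lhs <- (s$w_ext - s$w_ext[1]) + (s$w_thermo - s$w_thermo[1])
  rhs <- (s$e_kin + s$e_pot + s$e_diss) -
    (s$e_kin[1] + s$e_pot[1] + s$e_diss[1])
  w_scale <- max(abs(s$w_ext))
  expect_gt(w_scale, 0)
  expect_lt(max(abs(lhs - rhs)), 0.01 * w_scale)
})

test_that("broken-bond counters agree with the break log at every record", {
  m <- mk_small_fibril()
  mx <- insert_age_crosslinks(m, crosslink_spec(5, seed = 5))
  proto <- protocol_preset("desk", strain_limit = 0.4, record_interval = 200)
  run <- run_tension(mx, force_field(age_bond = age_bond(6, 25)), proto,
                     seed = 2)
  s <- run$series
  expect_gt(nrow(run$breaks), 0)
  for (i in seq_len(nrow(s))) {
    expect_equal(s$broken_age[i],
                 sum(run$breaks$type == "age" & run$breaks$step <= s$step[i]))
    expect_equal(s$broken_collagen[i],
                 sum(run$breaks$type == "backbone" &
                     run$breaks$step <= s$step[i]))
  }
  expect_true(all(diff(s$broken_age) >= 0))
  expect_true(all(diff(s$strain) >= 0))
})

test_that("quasi-static runs are bit-reproducible for a fixed seed", {
  m <- mk_small_fibril()
  mx <- insert_age_crosslinks(m, crosslink_spec(2, seed = 9))
  proto <- protocol_preset("quasistatic", strain_limit = 0.1,
                           equil_steps = 200, record_interval = 100)
  r1 <- run_tension(mx, force_field(), proto, seed = 7)
  r2 <- run_tension(mx, force_field(), proto, seed = 7)
  expect_identical(r1$series, r2$series)
})

test_that("engineering stress conversion is linear in force and inverse in area", {
  expect_equal(engineering_stress(0, 100), 0)
  expect_equal(engineering_stress(10, 200), engineering_stress(10, 100) / 2)
  # worked unit conversion: 1 kcal/mol/A over 1 A^2 = 6947.7 MPa
  # (4184 J/mol / 6.022e23 spread over 1e-20 m^2 and divided by 1e-10 m)
  expect_equal(engineering_stress(1, 1), 6947.7, tolerance = 1e-4)
})

test_that("malformed models are rejected", {
  m <- mk_two_chain()
  m$bonds$type[1] <- "mystery"
  expect_error(run_tension(m, force_field(),
                           tension_protocol(n_steps = 10, equil_steps = 0)),
               "unparameterized")
})
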