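# constructed observable series used as analytic oracles
mk_series <- function(strain, sigma, f_backbone = 0, ext_backbone = 0,
                      fgrip = 0, f_age = 0) {
  tibble::tibble(strain = strain, sigma = sigma,
                 f_backbone = f_backbone, ext_backbone = ext_backbone,
                 fgrip = fgrip, f_age = f_age)
}

test_that("elastic limit flags perfectly linear series and finds a constructed kink", {
  eps <- seq(0, 0.3, by = 0.002)
  lin <- mk_series(eps, 100 * eps)
  el <- elastic_limit(lin, smooth = 1)
  expect_true(el$censored)
  expect_equal(el$eps0, 0.3)
  kinked <- mk_series(eps, ifelse(eps <= 0.12, 100 * eps,
                                  12 + 20 * (eps - 0.12)))
  el2 <- elastic_limit(kinked, smooth = 1)
  expect_false(el2$censored)
  expect_equal(el2$eps0, 0.12, tolerance = 0.08)
  expect_equal(el2$slope, 100, tolerance = 1e-6)
})

test_that("peak metrics: softening gives no stiffening, constructed rise gives its gap", {
  eps <- seq(0, 0.3, by = 0.002)
  soften <- mk_series(eps, ifelse(eps <= 0.15, 100 * eps,
                                  15 - 30 * (eps - 0.15)))
  pk <- peak_metrics(soften, eps0 = 0.15, sigma0 = 15, smooth = 1)
  expect_lte(pk$delta_sigma, pk$noise_floor)
  expect_false(pk$stiffening)
  # second rise of known height: peak 15 + 18 at strain 0.27
  rise <- mk_series(eps, ifelse(eps <= 0.15, 100 * eps,
                                15 + 150 * (eps - 0.15)))
  pk2 <- peak_metrics(rise, eps0 = 0.15, sigma0 = 15, smooth = 1)
  expect_equal(pk2$delta_sigma, 150 * 0.15, tolerance = 1e-6)
  expect_true(pk2$stiffening)
  # identity holds exactly
  expect_equal(pk2$delta_sigma, pk2$sigma_peak - 15)
})

test_that("gap opening arithmetic and exact roundtrip", {
  s <- mk_series(strain = c(0, 0.01), sigma = 0, ext_backbone = 0)
  out <- gap_opening(s, g_mean = 402, n_tc = 217, r0 = 14)
  expect_equal(out$dg, c(0, 34.40))
  # roundtrip through the strain decomposition is exact
  set.seed(1)
  dg <- runif(20, 0, 50); ext <- runif(20, 0, 2)
  eps <- strain_from_gap(dg, ext, 402, 217, 14)
  back <- eps * (402 + 217 * 14) - 217 * ext
  expect_equal(back, dg, tolerance = 1e-12)
})

test_that("stretch energy reproduces constant and linear-ramp closed forms", {
  n <- 101
  ext <- seq(0, 2, length.out = n)
  eps <- seq(0, 0.2, length.out = n)
  const <- mk_series(eps, sigma = 0, f_backbone = 3, ext_backbone = ext)
  es <- stretch_energy(const, eps_to = 0.2, eps_from = 0)
  expect_equal(es$e_stretch, 3 * 2)
  ramp <- mk_series(eps, sigma = 0, f_backbone = 17.13 * ext,
                    ext_backbone = ext)
  es2 <- stretch_energy(ramp, eps_to = 0.2, eps_from = 0)
  expect_equal(es2$e_stretch, 0.5 * 17.13 * 2^2, tolerance = 1e-12)
})

test_that("slide energy: zero sliding force gives zero; constant friction gives force x travel", {
  n <- 101
  eps <- seq(0, 0.2, length.out = n)
  nul <- mk_series(eps, sigma = 0, f_backbone = 2, fgrip = 5 * 2)
  sl <- slide_energy(nul, eps_to = 0.2, n_sites = 5, g_mean = 402,
                     n_tc = 217, r0 = 14, eps_from = 0)
  expect_equal(sl$e_slide, 0)
  fric <- mk_series(eps, sigma = 0, f_backbone = 0, fgrip = 5 * 1.5)
  sl2 <- slide_energy(fric, eps_to = 0.2, n_sites = 5, g_mean = 402,
                      n_tc = 217, r0 = 14, eps_from = 0)
  travel <- 0.2 * (402 + 217 * 14)
  expect_equal(sl2$e_slide, 1.5 * travel, tolerance = 1e-12)
})

test_that("broken-bond census percentages", {
  m <- mk_dimer()
  m$n_age_inserted <- 10L
  m$n_molecules <- 4
  empty <- tibble::tibble(step = integer(0), bond = integer(0),
                          type = character(0))
  expect_equal(broken_bond_census(empty, m)$broken_age_pct, 0)
  expect_equal(broken_bond_census(empty, m)$broken_col_ratio, 0)
  log3 <- tibble::tibble(step = 1:8, bond = 1:8,
                         type = c(rep("age", 3), rep("backbone", 5)))
  cen <- broken_bond_census(log3, m)
  expect_equal(cen$broken_age_pct, 30)
  expect_equal(cen$broken_col_ratio, 125)  # may exceed 100
})

test_that("phase map boundary solves the energy balance and classifies cells", {
  wtc <- loading_energy_capacity(collagen_bond())
  grid <- expand.grid(k1 = c(6, 12, 24), rbreak = c(25, 35, 60),
                      n_age = c(0, 2, 10))
  grid$wage <- NA
  grid$stiffening <- with(grid, ifelse(
    n_age == 0, FALSE,
    mapply(function(k, r, na)
      na * loading_energy_capacity(age_bond(k, r)) > wtc,
      k1, rbreak, n_age)))
  pm <- phase_map(grid, wtc = wtc)
  expect_equal(pm$agreement, 1)  # classification built from the criterion
  expect_false(any(pm$cells$predicted[pm$cells$n_age == 0]))
  # boundary points satisfy n_age * W(k1, rbreak*) = wtc (root-find oracle)
  bnd <- pm$boundary[!is.na(pm$boundary$rbreak), ]
  w_at <- mapply(function(k, r) loading_energy_capacity(age_bond(k, r)),
                 bnd$k1, bnd$rbreak)
  expect_equal(bnd$n_age * w_at, rep(wtc, nrow(bnd)), tolerance = 1e-5)
  # no boundary when only the cross-link-free density is present
  pm0 <- phase_map(grid[grid$n_age == 0, ], wtc = wtc)
  expect_equal(nrow(pm0$boundary), 0L)
  expect_false(any(pm0$cells$observed != pm0$cells$predicted))
})

test_that("transition strain detection handles crossing and non-crossing series", {
  eps <- seq(0, 0.3, length.out = 61)
  # molecular strain overtakes fibrillar strain at 0.2
  ext <- 14 * ifelse(eps < 0.2, 0.8 * eps, 0.8 * 0.2 + 2.0 * (eps - 0.2))
  s <- mk_series(eps, sigma = 0, f_backbone = 1, ext_backbone = ext)
  st <- stretch_energy(s, eps_to = 0.3)
  expect_false(st$eps_star_flagged)
  expect_equal(st$eps_star, 0.24, tolerance = 0.05)
  # never crosses: flagged, integration from zero
  s2 <- mk_series(eps, sigma = 0, f_backbone = 1, ext_backbone = 14 * 0.5 * eps)
  st2 <- stretch_energy(s2, eps_to = 0.3)
  expect_true(st2$eps_star_flagged)
  expect_equal(st2$eps_star, 0)
})
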