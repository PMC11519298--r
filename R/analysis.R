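# trapezoidal integral of y over (possibly non-uniform, non-monotone) x
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Elastic limit of a stress-strain series
#'
#' Fits a least-squares line to the (lightly smoothed) stress over the
#' initial strain window and reports the first strain beyond the window at
#' which the stress deviates from the fit by more than `tol` relative — the
#' limit of the linear elastic regime. If no deviation occurs before the end
#' of the series the last strain is returned with `censored = TRUE`.
#'
#' @param series Observable tibble from [run_tension()] (columns `strain`,
#'   `sigma`).
#' @param fit_range Strain window of the linear fit; default `c(0.02, 0.10)`.
#' @param tol Relative deviation declaring the end of linearity; default
#'   0.02.
#' @param smooth Centered moving-average window (records) applied to the
#'   stress before fitting and detection; default 5.
#' @return One-row tibble: `eps0`, `sigma0` (stress interpolated at `eps0`),
#'   `slope` of the linear fit, `censored`.
#' @export
elastic_limit <- function(series, fit_range = c(0.02, 0.10), tol = 0.02,
                          smooth = 5) {
  stopifnot(is.data.frame(series), all(c("strain", "sigma") %in% names(series)))
  eps <- series$strain
  if (max(eps) < 0.2) {
    warning("series covers strain < 0.2; elastic limit may be censored",
            call. = FALSE)
  }
  sig <- .movavg(series$sigma, smooth)
  in_fit <- eps >= fit_range[1] & eps <= fit_range[2]
  if (sum(in_fit) < 3) stop("too few records in the fit window", call. = FALSE)
  fit <- stats::lm(sig[in_fit] ~ eps[in_fit])
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  pred <- a + b * eps
  # departure must exceed both the relative band and the stress noise of the
  # fit window (3 residual SDs), for two consecutive records
  noise <- 3 * stats::sd(stats::residuals(fit))
  thresh <- pmax(tol * pmax(abs(pred), 1e-10), noise)
  scan <- which(eps > fit_range[2])
  dev_ok <- abs(sig[scan] - pred[scan]) > thresh[scan]
  dev2 <- dev_ok & c(dev_ok[-1], FALSE)
  if (any(dev2)) {
    idx <- scan[which(dev2)[1]]
    eps0 <- eps[idx]
    censored <- FALSE
  } else {
    eps0 <- eps[length(eps)]
    censored <- TRUE
  }
  sigma0 <- stats::approx(eps, sig, xout = eps0, rule = 2)$y
  tibble::tibble(eps0 = eps0, sigma0 = sigma0, slope = b, censored = censored)
}

#' Peak and stiffening metrics
#'
#' Global stress maximum of the (smoothed) stress-strain curve and the
#' elastic-to-peak stress difference `delta_sigma = sigma_peak - sigma0`.
#' A run is classified as stiffening when `delta_sigma` exceeds the noise
#' floor *and* the peak lies beyond the elastic limit by more than
#' `min_rise` strain — a sustained post-elastic hardening regime rather
#' than a residual rise within the detection uncertainty of `eps0`.
#'
#' @inheritParams elastic_limit
#' @param eps0,sigma0 Elastic limit, e.g. from [elastic_limit()].
#' @param noise_floor Stress resolution (MPa) below which `delta_sigma`
#'   counts as no stiffening; default `max(5, 0.10 * sigma0)`, the
#'   detection resolution of the elastic-limit rule (whose departure band is
#'   three residual standard deviations of the linear fit, typically 6-8% of
#'   `sigma0` at desk scale, plus smoothing bias).
#' @param min_rise Minimum strain interval between `eps0` and the peak for
#'   the stiffening classification; default 0.05, the detection uncertainty
#'   of the elastic limit itself.
#' @return One-row tibble: `sigma_peak`, `eps_peak`, `delta_sigma`,
#'   `stiffening`, `noise_floor`.
#' @export
peak_metrics <- function(series, eps0, sigma0, noise_floor = NULL, smooth = 5,
                         min_rise = 0.05) {
  stopifnot(is.data.frame(series))
  sig <- .movavg(series$sigma, smooth)
  i <- which.max(sig)
  sigma_peak <- sig[i]
  eps_peak <- series$strain[i]
  delta <- sigma_peak - sigma0
  if (is.null(noise_floor)) noise_floor <- max(5, 0.10 * sigma0)
  tibble::tibble(sigma_peak = sigma_peak, eps_peak = eps_peak,
                 delta_sigma = delta,
                 stiffening = delta > noise_floor & (eps_peak - eps0) > min_rise,
                 noise_floor = noise_floor)
}

#' Gap opening from global strain
#'
#' Kinematic estimate of the change in gap size between consecutive
#' molecules: the global strain is decomposed into mean bond stretching and
#' gap opening,
#' `strain = (dg + n_tc * <r - r0>) / (g_mean + n_tc * r0)`,
#' so `dg = strain * (g_mean + n_tc * r0) - n_tc * <r - r0>`.
#'
#' @param series Observable tibble (columns `strain`, `ext_backbone`).
#' @param g_mean Initial mean gap length (Å).
#' @param n_tc Bonds per tropocollagen molecule.
#' @param r0 Equilibrium backbone bond length (Å).
#' @return The series with a `dg` column appended.
#' @export
gap_opening <- function(series, g_mean, n_tc, r0) {
  stopifnot(is.data.frame(series),
            all(c("strain", "ext_backbone") %in% names(series)))
  dplyr::mutate(series,
                dg = .data$strain * (g_mean + n_tc * r0) - n_tc * .data$ext_backbone)
}

#' Invert the gap-opening decomposition
#'
#' Recovers the global strain from a gap opening and mean bond extension;
#' exact inverse of [gap_opening()].
#'
#' @param dg Gap opening (Å).
#' @param ext Mean bond extension `<r - r0>` (Å).
#' @inheritParams gap_opening
#' @return Strain.
#' @export
strain_from_gap <- function(dg, ext, g_mean, n_tc, r0) {
  (dg + n_tc * ext) / (g_mean + n_tc * r0)
}

# first strain at which the molecular strain reaches the fibrillar strain:
# the approximate transition from sliding/rearrangement-dominated to
# stretching-dominated deformation. Returns 0 (flagged) when no crossing.
.eps_star <- function(series, r0, min_strain = 0.01) {
  eps <- series$strain
  eps_tc <- series$ext_backbone / r0
  d <- eps_tc - eps
  # upward crossing: molecular strain catches up with the fibrillar strain
  # (the initial pair-interaction pre-tension makes d slightly positive at
  # zero strain, so a sign condition alone would fire immediately)
  up <- c(FALSE, d[-1] >= 0 & d[-length(d)] < 0)
  cand <- which(up & eps > min_strain)
  if (length(cand) == 0) {
    return(list(eps_star = 0, flagged = TRUE, idx = 1L))
  }
  list(eps_star = eps[cand[1]], flagged = FALSE, idx = cand[1])
}

#' Energy absorbed by molecular stretching
#'
#' Trapezoidal integral of the mean backbone bond force over the mean bond
#' extension, from the sliding-to-stretching transition strain (first
#' crossing of fibrillar and molecular strain; 0 with a flag when no
#' crossing occurs) up to `eps_to`, scaled per molecule by the number of
#' bonds. Reported per backbone bond (kcal mol^-1 per bond) unless
#' `per_molecule`.
#'
#' @param series Observable tibble (columns `strain`, `f_backbone`,
#'   `ext_backbone`).
#' @param eps_to Upper strain bound (typically the strain at peak stress).
#' @param r0 Equilibrium backbone bond length (Å).
#' @param eps_from Lower strain bound; `NULL` (default) uses the transition
#'   strain.
#' @return One-row tibble: `e_stretch`, `eps_star`, `eps_star_flagged`.
#' @export
stretch_energy <- function(series, eps_to, r0 = 14, eps_from = NULL) {
  stopifnot(is.data.frame(series))
  if (is.null(eps_from)) {
    st <- .eps_star(series, r0)
    eps_from <- st$eps_star
    flagged <- st$flagged
  } else {
    flagged <- FALSE
  }
  keep <- series$strain >= eps_from & series$strain <= eps_to
  e <- .trapz(series$ext_backbone[keep], series$f_backbone[keep])
  tibble::tibble(e_stretch = max(0, e), eps_star = eps_from,
                 eps_star_flagged = flagged)
}

#' Energy dissipated by inter-molecular sliding
#'
#' Heuristic sliding dissipation: the per-molecule sliding force is the
#' globally applied force divided by the number of molecules in the
#' cross-section, reduced by the mean backbone stretching force (floored at
#' zero — negative balances are treated as measurement noise of the force
#' decomposition), integrated over the gap opening [gap_opening()] from the
#' transition strain to `eps_to`.
#'
#' @inheritParams stretch_energy
#' @param n_sites Molecules in the cross-section.
#' @param g_mean,n_tc See [gap_opening()].
#' @param floor_fslide Floor negative sliding forces at zero (default TRUE).
#' @return One-row tibble: `e_slide`, `eps_star`, `eps_star_flagged`.
#' @export
slide_energy <- function(series, eps_to, n_sites, g_mean, n_tc, r0 = 14,
                         eps_from = NULL, floor_fslide = TRUE) {
  stopifnot(is.data.frame(series), n_sites >= 1)
  if (is.null(eps_from)) {
    st <- .eps_star(series, r0)
    eps_from <- st$eps_star
    flagged <- st$flagged
  } else {
    flagged <- FALSE
  }
  ser <- gap_opening(series, g_mean, n_tc, r0)
  fslide <- ser$fgrip / n_sites - ser$f_backbone
  if (floor_fslide) fslide <- pmax(0, fslide)
  keep <- ser$strain >= eps_from & ser$strain <= eps_to
  e <- .trapz(ser$dg[keep], fslide[keep])
  tibble::tibble(e_slide = max(0, e), eps_star = eps_from,
                 eps_star_flagged = flagged)
}

#' Broken-bond census
#'
#' Percentage of inserted cross-links broken, and broken backbone bonds as a
#' percentage of the molecule count (a molecule can break more than once, so
#' this ratio may exceed 100).
#'
#' @param breaks Break-log tibble from a [run_tension()] result.
#' @param model The fibril model of the run.
#' @return One-row tibble: `broken_age_pct`, `broken_col_ratio`.
#' @export
broken_bond_census <- function(breaks, model) {
  stopifnot(is.data.frame(breaks), inherits(model, "fibril_model"))
  n_age_broken <- sum(breaks$type == "age")
  n_col_broken <- sum(breaks$type == "backbone")
  tibble::tibble(
    broken_age_pct = if (model$n_age_inserted > 0)
      100 * n_age_broken / model$n_age_inserted else 0,
    broken_col_ratio = 100 * n_col_broken / model$n_molecules)
}

#' Derived mechanical metrics of a tensile run
#'
#' Computes the elastic limit, peak/stiffening metrics, energy partition and
#' broken-bond census of a completed tensile test, optionally normalizing
#' the sliding and stretching energies by a zero-cross-link reference run of
#' the same geometry and protocol.
#'
#' @param run A `tension_run`.
#' @param reference Optional `tension_run` with `n_age = 0` providing
#'   `e_slide0` / `e_stretch0` for the normalized energies.
#' @param noise_floor,fit_range,tol,smooth Passed to [elastic_limit()] and
#'   [peak_metrics()].
#' @return One-row tibble of metrics (class retains plain tibble semantics).
#' @export
fibril_metrics <- function(run, reference = NULL, noise_floor = NULL,
                           fit_range = c(0.02, 0.10), tol = 0.02, smooth = 5) {
  stopifnot(inherits(run, "tension_run"))
  ser <- run$series
  model <- run$model
  r0 <- run$ff$collagen_bond$r0
  el <- elastic_limit(ser, fit_range = fit_range, tol = tol, smooth = smooth)
  pk <- peak_metrics(ser, el$eps0, el$sigma0, noise_floor = noise_floor,
                     smooth = smooth)
  n_tc <- model$n_body_bonds_per_chain
  es <- stretch_energy(ser, eps_to = pk$eps_peak, r0 = r0)
  eg <- slide_energy(ser, eps_to = pk$eps_peak, n_sites = model$n_sites,
                     g_mean = model$g_mean, n_tc = n_tc, r0 = r0)
  cen <- broken_bond_census(run$breaks, model)
  i_peak <- which.min(abs(ser$strain - pk$eps_peak))
  out <- dplyr::bind_cols(
    el[, c("eps0", "sigma0", "slope", "censored")], pk[, 1:4], es[, 1],
    eg[, 1], tibble::tibble(eps_star = es$eps_star,
                            eps_star_flagged = es$eps_star_flagged),
    cen,
    tibble::tibble(f_age_peak = ser$f_age[i_peak],
                   n_age_inserted = model$n_age_inserted))
  if (!is.null(reference)) {
    refm <- if (inherits(reference, "tension_run")) {
      fibril_metrics(reference, noise_floor = noise_floor,
                     fit_range = fit_range, tol = tol, smooth = smooth)
    } else {
      stopifnot(is.data.frame(reference),
                all(c("e_stretch", "e_slide") %in% names(reference)))
      reference
    }
    out$e_stretch_norm <- ifelse(refm$e_stretch > 0,
                                 out$e_stretch / refm$e_stretch, NA_real_)
    out$e_slide_norm <- ifelse(refm$e_slide > 0,
                               out$e_slide / refm$e_slide, NA_real_)
  }
  out
}

#' Stiffening phase map
#'
#' Combines sweep results into a (k1, rbreak) phase map per cross-link
#' density: each cell is classified as stiffening when its measured
#' elastic-to-peak stress difference exceeds the noise floor, and compared
#' with the theoretical criterion `n_age * W_age > W_tc`. The theoretical
#' boundary curve `n_age * W(k1, rbreak) = W_tc` is solved for rbreak at a
#' fine k1 grid.
#'
#' @param results Tibble with columns `k1`, `rbreak`, `n_age` and either
#'   `stiffening` (logical) or `delta_sigma`.
#' @param wtc Backbone loading energy capacity (kcal mol^-1 per bond), e.g.
#'   `loading_energy_capacity(collagen_bond())`.
#' @param noise_floor Used only when `stiffening` is absent; MPa.
#' @return Object of class `phase_map`: list with `cells` (adds `wage`,
#'   `predicted`, `observed`, `agree`), `boundary` (k1, rbreak per n_age),
#'   `agreement` (fraction of cells where prediction and observation agree),
#'   `wtc`.
#' @export
phase_map <- function(results, wtc, noise_floor = 2) {
  stopifnot(is.data.frame(results), wtc > 0,
            all(c("k1", "rbreak", "n_age") %in% names(results)))
  cells <- dplyr::as_tibble(results)
  cells$wage <- purrr::map2_dbl(cells$k1, cells$rbreak, function(k1, rb) {
    if (is.na(k1) || is.na(rb)) NA_real_
    else loading_energy_capacity(age_bond(k1, rb))
  })
  # the energy balance is a linear-density criterion: on scaled geometries
  # use the full-length-equivalent density when the sweep provides it
  dens_eff <- if ("n_age_eff" %in% names(cells)) cells$n_age_eff else cells$n_age
  cells$predicted <- ifelse(
    dens_eff == 0, FALSE,
    stiffening_ratio(wtc, dens_eff, cells$wage) > 1)
  if (!"stiffening" %in% names(cells)) {
    cells$stiffening <- cells$delta_sigma > noise_floor
  }
  cells$observed <- cells$stiffening
  cells$agree <- cells$predicted == cells$observed
  dens_tbl <- dplyr::distinct(
    tibble::tibble(n_age = cells$n_age, eff = dens_eff))
  dens_tbl <- dens_tbl[dens_tbl$n_age > 0, ]
  k1_ok <- cells$k1[!is.na(cells$k1)]
  if (length(k1_ok) == 0) k1_ok <- c(6, 24)
  k1_grid <- seq(min(k1_ok), max(k1_ok), length.out = 60)
  boundary <- purrr::map2_dfr(dens_tbl$n_age, dens_tbl$eff, function(na, eff) {
    rb <- vapply(k1_grid, function(k1) {
      f <- function(r) eff * loading_energy_capacity(age_bond(k1, r)) - wtc
      lo <- 22.72 + 1e-6; hi <- 500
      if (f(hi) < 0) return(NA_real_)
      if (f(lo) > 0) return(lo)
      stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
    }, 0)
    tibble::tibble(n_age = na, k1 = k1_grid, rbreak = rb)
  })
  structure(list(cells = cells, boundary = boundary,
                 agreement = mean(cells$agree), wtc = wtc),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d cells, W_TC = %.4g kcal/mol, agreement %.1f%%\n",
              nrow(x$cells), x$wtc, 100 * x$agreement))
  invisible(x)
}
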