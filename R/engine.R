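#' Constant-velocity tensile-test protocol
#'
#' Parameters of the steered tensile test: the two grip regions are
#' constrained and moved apart symmetrically at `pull_speed / 2` each, after
#' an optional thermostatted equilibration with static grips.
#'
#' @param pull_speed Total separation rate (Å fs^-1); reference value 1e-4
#'   (= 10 m/s).
#' @param dt Integration timestep (fs); reference value 1.
#' @param temperature Langevin thermostat temperature (K); 0 together with a
#'   positive `damping` gives deterministic quasi-static (viscous) dynamics,
#'   0 with `damping = 0` gives NVE.
#' @param damping Langevin damping time (fs); 0 disables the thermostat.
#' @param record_interval Steps between observable records.
#' @param strain_limit Engineering strain at which the test ends.
#' @param collapse_frac If > 0, the run also ends once the recorded grip
#'   force falls below this fraction of its running peak (post-failure
#'   stress collapse), checked for strains above `collapse_min_strain`.
#' @param collapse_min_strain See `collapse_frac`.
#' @param equil_steps Thermostatted equilibration steps before pulling.
#' @param n_steps Explicit number of pulling steps; `NULL` (default) derives
#'   the count from `strain_limit`.
#' @return An object of class `tension_protocol`.
#' @export
tension_protocol <- function(pull_speed = 1e-4, dt = 1, temperature = 300,
                             damping = 1000, record_interval = 1000,
                             strain_limit = 0.35, collapse_frac = 0,
                             collapse_min_strain = 0.1, equil_steps = 5000,
                             n_steps = NULL) {
  stopifnot(pull_speed >= 0, dt > 0, temperature >= 0, damping >= 0,
            record_interval >= 1, strain_limit > 0)
  structure(list(pull_speed = pull_speed, dt = dt, temperature = temperature,
                 damping = damping, record_interval = as.integer(record_interval),
                 strain_limit = strain_limit, collapse_frac = collapse_frac,
                 collapse_min_strain = collapse_min_strain,
                 equil_steps = as.integer(equil_steps),
                 n_steps = if (is.null(n_steps)) -1L else as.integer(n_steps)),
            class = "tension_protocol")
}

#' Named tensile protocols
#'
#' * `"reference"` — 1e-4 Å/fs (10 m/s), 1 fs timestep, 300 K.
#' * `"desk"` — desk-scale protocol for the reduced specimens: 50x faster
#'   pulling and a 2 fs timestep (still ~400 steps per backbone vibration
#'   period), 300 K.
#' * `"quasistatic"` — desk-scale speed at 0 K with viscous damping:
#'   fully deterministic runs for engine checks.
#'
#' @param name Protocol name.
#' @param ... Overrides passed to [tension_protocol()].
#' @return A `tension_protocol`.
#' @export
protocol_preset <- function(name = c("desk", "reference", "quasistatic"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    reference = list(pull_speed = 1e-4, dt = 1, temperature = 300,
                 damping = 1000, record_interval = 2000, equil_steps = 20000),
    # damping is scaled with the 50x pulling speed-up so that the viscous
    # drag per chain stays small against the bond forces (the thermostat
    # friction acts on the systematic flow field as well)
    desk = list(pull_speed = 5e-3, dt = 2, temperature = 300,
                damping = 50000, record_interval = 250, equil_steps = 4000),
    quasistatic = list(pull_speed = 5e-3, dt = 2, temperature = 0,
                       damping = 20000, record_interval = 250,
                       equil_steps = 2000)
  )
  do.call(tension_protocol, utils::modifyList(base, list(...)))
}

# consecutive-triplet angle list (per chain, extensions included)
.angle_triplets <- function(model) {
  p <- model$particles
  n <- nrow(p)
  if (n < 3) return(matrix(integer(0), ncol = 3))
  i <- p$id[1:(n - 2)]; j <- p$id[2:(n - 1)]; k <- p$id[3:n]
  ok <- p$chain[1:(n - 2)] == p$chain[2:(n - 1)] &
    p$chain[2:(n - 1)] == p$chain[3:n]
  cbind(i[ok], j[ok], k[ok])
}

.bond_par_row <- function(p) {
  c(p$r0, p$r1, p$rbreak, p$k0, p$k1, p$a)
}

# shared marshalling + engine call
.run_engine <- function(model, ff, protocol, seed, v0 = NULL) {
  stopifnot(inherits(model, "fibril_model"), inherits(ff, "force_field"),
            inherits(protocol, "tension_protocol"))
  p <- model$particles
  coords <- cbind(p$x, p$y, p$z)
  grip <- integer(nrow(p))
  grip[model$grips$left] <- 1L
  grip[model$grips$right] <- 2L
  type_code <- c(backbone = 1L, end = 2L, age = 3L)[model$bonds$type]
  if (anyNA(type_code)) stop("unparameterized bond type in model", call. = FALSE)
  bond_par <- rbind(.bond_par_row(ff$collagen_bond),
                    .bond_par_row(ff$end_bond),
                    .bond_par_row(ff$age_bond))
  ang <- .angle_triplets(model)
  proto <- unclass(protocol)
  proto$l0 <- model$l0
  # stretching observables are averaged over backbone bonds of the fully
  # banded interior (all stagger phases present); near the fibril ends only
  # a subset of phases exists and those bonds carry concentrated loads that
  # would bias the per-molecule force estimate
  body_z <- p$z[p$kind == "body"]
  ramp <- (model$config$n_stagger - 1) * model$config$d_period
  z_lo <- min(body_z) + ramp
  z_hi <- max(body_z) - ramp
  obs <- model$bonds$type == "backbone" &
    p$z[model$bonds$i] >= z_lo & p$z[model$bonds$i] <= z_hi &
    p$z[model$bonds$j] >= z_lo & p$z[model$bonds$j] <= z_hi
  if (!any(obs)) obs <- model$bonds$type == "backbone"
  res <- md_run_cpp(coords, grip, ff$mass,
                    as.matrix(model$bonds[, c("i", "j")]), type_code,
                    as.integer(obs), bond_par, ang,
                    ff$angle$k_theta, ff$angle$theta0,
                    ff$nonbonded$sigma, ff$nonbonded$epsilon,
                    ff$nonbonded$cutoff, proto, as.integer(seed), v0)
  res
}

#' Run a destructive tensile test
#'
#' Integrates the fibril under the force field with velocity-Verlet dynamics
#' while the two grip regions move apart at constant velocity, removing
#' bonds permanently once they stretch beyond `rbreak + a`, and recording
#' engineering strain and stress, mean bond forces and extensions, broken
#' bond counts and an energy ledger at fixed intervals.
#'
#' @param model A [fibril_model][build_fibril] (with or without cross-links).
#' @param ff A [force_field()].
#' @param protocol A [tension_protocol()].
#' @param seed Integer seed for velocity initialization and thermostat noise
#'   (geometry seeds live in [crosslink_spec()]).
#' @return An object of class `tension_run`: list with `series` (tibble of
#'   per-record observables, stress in MPa), `breaks` (tibble log of bond
#'   removals), `final` (coordinates, velocities, alive flags), and the
#'   inputs. `tidy()` returns the series, `glance()` the derived metrics.
#' @export
run_tension <- function(model, ff = force_field(), protocol = protocol_preset("desk"),
                        seed = 1L) {
  res <- .run_engine(model, ff, protocol, seed)
  series <- tibble::as_tibble(res$series)
  series$sigma <- engineering_stress(series$fgrip, model$a0)
  breaks <- tibble::as_tibble(res$breaks)
  breaks$type <- c("backbone", "end", "age")[breaks$type]
  structure(list(series = series, breaks = breaks,
                 final = list(coords = res$coords, velocities = res$velocities,
                              alive = res$alive),
                 model = model, ff = ff, protocol = protocol, seed = seed),
            class = "tension_run")
}

#' @export
print.tension_run <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    paste0("<tension_run> %d records to strain %.3f; peak stress %.4g MPa\n",
           "  broken: %d AGE, %d backbone bonds\n"),
    nrow(s), max(s$strain), max(s$sigma),
    utils::tail(s$broken_age, 1), utils::tail(s$broken_collagen, 1)))
  invisible(x)
}

#' Convert grip force to engineering stress
#'
#' `sigma = F / A0`, converted from kcal mol^-1 Å^-3 to MPa with the factor
#' 6947.7 (1 kcal mol^-1 Å^-3 = 6947.7 MPa).
#'
#' @param force Total grip force (kcal mol^-1 Å^-1).
#' @param a0 Initial cross-section area (Å^2).
#' @return Engineering stress (MPa).
#' @export
engineering_stress <- function(force, a0) {
  stopifnot(a0 > 0)
  force / a0 * 6947.7
}

#' Plain NVE integration (testing interface)
#'
#' Integrates the model without thermostat, pulling or grip motion for
#' `n_steps` steps; used to verify integrator health (energy conservation,
#' vibration periods).
#'
#' @param model A `fibril_model`.
#' @param ff A [force_field()].
#' @param n_steps Number of steps.
#' @param dt Timestep (fs).
#' @param v0 Optional n-by-3 matrix of initial velocities (Å fs^-1).
#' @param record_interval Steps between records.
#' @return A `tension_run` (with zero strain throughout).
#' @export
step_nve <- function(model, ff = force_field(), n_steps, dt = 1, v0 = NULL,
                     record_interval = 100) {
  proto <- tension_protocol(pull_speed = 0, dt = dt, temperature = 0,
                            damping = 0, record_interval = record_interval,
                            equil_steps = 0, n_steps = n_steps)
  res <- .run_engine(model, ff, proto, seed = 1L, v0 = v0)
  series <- tibble::as_tibble(res$series)
  series$sigma <- engineering_stress(series$fgrip, model$a0)
  breaks <- tibble::as_tibble(res$breaks)
  structure(list(series = series, breaks = breaks,
                 final = list(coords = res$coords, velocities = res$velocities,
                              alive = res$alive),
                 model = model, ff = ff, protocol = proto, seed = 1L),
            class = "tension_run")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_tension
#' @param x A `tension_run`.
#' @param ... Unused.
#' @method tidy tension_run
#' @export
tidy.tension_run <- function(x, ...) x$series

#' @rdname run_tension
#' @method glance tension_run
#' @export
glance.tension_run <- function(x, ...) fibril_metrics(x)
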