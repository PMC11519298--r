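#' Breakable trilinear bond parameters
#'
#' Constructs the parameter set of the piecewise-linear breakable bond law
#' used for both collagen backbone bonds and AGE cross-links. The restoring
#' force magnitude rises with slope `k0` from the equilibrium distance `r0`
#' to the critical hyperelastic distance `r1`, then with slope `k1` up to the
#' breaking distance `rbreak`, and finally ramps linearly back to zero over a
#' regularization length `a = z * (rbreak - r1)` so that both force and
#' energy are continuous through failure. A bond whose length ever reaches
#' `rbreak + a` is considered broken irreversibly.
#'
#' @param r0 Equilibrium distance (Å).
#' @param r1 Critical hyperelastic distance (Å), `r0 < r1`.
#' @param rbreak Bond breaking distance (Å), `r1 < rbreak`. May be `Inf` for
#'   unbreakable (end-strengthened) bonds.
#' @param k0 First-regime stiffness (kcal mol^-1 Å^-2).
#' @param k1 Second-regime stiffness (kcal mol^-1 Å^-2).
#' @param z Dimensionless regularization factor defining the post-break
#'   unloading length `a = z * (rbreak - r1)`. Default 0.1.
#'
#' @return An object of class `trilinear_bond` (named list with fields
#'   `r0, r1, rbreak, k0, k1, z, a`).
#' @examples
#' glu <- glucosepane_bond()
#' bond_force(glu, c(18.52, 22.72, 31.72))
#' loading_energy_capacity(glu)
#' @export
trilinear_bond <- function(r0, r1, rbreak, k0, k1, z = 0.1) {
  stopifnot(is.numeric(r0), is.numeric(r1), is.numeric(rbreak),
            is.numeric(k0), is.numeric(k1), is.numeric(z))
  if (!(r0 > 0 && r1 > r0 && rbreak > r1)) {
    stop("invalid bond parameters: need 0 < r0 < r1 < rbreak", call. = FALSE)
  }
  if (!(k0 > 0 && k1 > 0 && z > 0)) {
    stop("invalid bond parameters: need k0 > 0, k1 > 0, z > 0", call. = FALSE)
  }
  structure(
    list(r0 = r0, r1 = r1, rbreak = rbreak, k0 = k0, k1 = k1, z = z,
         a = z * (rbreak - r1)),
    class = "trilinear_bond"
  )
}

#' @export
print.trilinear_bond <- function(x, ...) {
  cat(sprintf(
    "<trilinear_bond> r0=%.3g r1=%.3g rbreak=%.4g k0=%.3g k1=%.3g z=%.3g\n",
    x$r0, x$r1, x$rbreak, x$k0, x$k1, x$z))
  if (is.finite(x$rbreak)) {
    cat(sprintf("  loading energy capacity W = %.4g kcal/mol\n",
                loading_energy_capacity(x)))
  } else {
    cat("  unbreakable (rbreak = Inf)\n")
  }
  invisible(x)
}

#' Reference AGE cross-link parameter sets
#'
#' `glucosepane_bond()` returns the glucosepane reference cross-link
#' (r0 = 18.52 Å, r1 = 22.72 Å, rbreak = 31.72 Å, k0 = 0.1,
#' k1 = 8.0 kcal mol^-1 Å^-2). `age_bond()` returns the same cross-link
#' geometry with user-chosen stiffness `k1` and breaking distance `rbreak`,
#' the two properties varied in the sweep design.
#'
#' @param k1,rbreak Second-regime stiffness and breaking distance.
#' @param z Regularization factor, see [trilinear_bond()].
#' @return A `trilinear_bond` object.
#' @export
glucosepane_bond <- function(z = 0.1) {
  trilinear_bond(r0 = 18.52, r1 = 22.72, rbreak = 31.72, k0 = 0.1, k1 = 8.0,
                 z = z)
}

#' @rdname glucosepane_bond
#' @export
age_bond <- function(k1, rbreak, z = 0.1) {
  trilinear_bond(r0 = 18.52, r1 = 22.72, rbreak = rbreak, k0 = 0.1, k1 = k1,
                 z = z)
}

#' Default collagen backbone bond
#'
#' Two-regime breakable bond for consecutive beads of a tropocollagen chain,
#' in the style of published mesoscale collagen force fields: soft
#' entropic-like regime up to r1, stiff backbone-stretching regime up to a
#' finite rbreak so backbone bonds can fracture under load transfer from
#' cross-links.
#'
#' @inheritParams glucosepane_bond
#' @return A `trilinear_bond` object.
#' @export
collagen_bond <- function(z = 0.1) {
  trilinear_bond(r0 = 14.0, r1 = 18.2, rbreak = 21.0, k0 = 17.13, k1 = 97.3,
                 z = z)
}

#' Strengthened unbreakable end bond
#'
#' Bond used in the grip extension regions; same stiffness as the backbone
#' but with an infinite breaking distance so that the specimen never fails
#' inside the grips.
#' @return A `trilinear_bond`-like object with `rbreak = Inf`.
#' @export
end_bond <- function() {
  p <- collagen_bond()
  p$rbreak <- Inf
  p$a <- Inf
  p
}

# magnitude of the restoring force (>= 0) on the tensile side; helper shared
# by bond_force and bond_energy
.tl_force_mag <- function(p, r) {
  d1 <- p$r1 - p$r0
  fmax <- p$k0 * d1 + p$k1 * (p$rbreak - p$r1)
  mag <- numeric(length(r))
  i1 <- r >= p$r0 & r < p$r1
  i2 <- r >= p$r1 & r < p$rbreak
  i3 <- is.finite(p$rbreak) & r >= p$rbreak & r < p$rbreak + p$a
  mag[i1] <- p$k0 * (r[i1] - p$r0)
  mag[i2] <- p$k0 * d1 + p$k1 * (r[i2] - p$r1)
  mag[i3] <- fmax * (1 - (r[i3] - p$rbreak) / p$a)
  mag
}

#' Trilinear bond force
#'
#' Signed bond force as a function of inter-particle distance: negative
#' values are restoring (attractive) for `r > r0`, positive values repulsive
#' for `r < r0` (compressive side responds with stiffness `k0` and never
#' breaks). The magnitude is `k0 (r - r0)` on `[r0, r1)`,
#' `k0 (r1 - r0) + k1 (r - r1)` on `[r1, rbreak)`, a linear ramp back to zero
#' on `[rbreak, rbreak + a)`, and zero beyond.
#'
#' @param p A [trilinear_bond()] parameter object.
#' @param r Distance(s), Å, `r >= 0`.
#' @return Signed force (kcal mol^-1 Å^-1), vectorized over `r`.
#' @export
bond_force <- function(p, r) {
  stopifnot(inherits(p, "trilinear_bond"), is.numeric(r), all(r >= 0))
  f <- -.tl_force_mag(p, r)
  ic <- r < p$r0
  f[ic] <- -p$k0 * (r[ic] - p$r0)
  f
}

#' Trilinear bond energy
#'
#' Potential energy of the breakable bond, the negative integral of
#' [bond_force()] from `r0`: zero at equilibrium, monotone non-decreasing on
#' the tensile side, and constant (fully dissipated) beyond `rbreak + a`.
#'
#' @inheritParams bond_force
#' @return Energy (kcal mol^-1), vectorized over `r`.
#' @export
bond_energy <- function(p, r) {
  stopifnot(inherits(p, "trilinear_bond"), is.numeric(r), all(r >= 0))
  d1 <- p$r1 - p$r0
  fmax <- p$k0 * d1 + p$k1 * (p$rbreak - p$r1)
  w <- if (is.finite(p$rbreak)) loading_energy_capacity(p) else Inf
  e <- numeric(length(r))
  ic <- r < p$r0
  i1 <- r >= p$r0 & r < p$r1
  i2 <- r >= p$r1 & r < p$rbreak
  i3 <- is.finite(p$rbreak) & r >= p$rbreak & r < p$rbreak + p$a
  i4 <- is.finite(p$rbreak) & r >= p$rbreak + p$a
  e[ic] <- 0.5 * p$k0 * (r[ic] - p$r0)^2
  e[i1] <- 0.5 * p$k0 * (r[i1] - p$r0)^2
  e[i2] <- 0.5 * p$k0 * d1^2 + p$k0 * d1 * (r[i2] - p$r1) +
    0.5 * p$k1 * (r[i2] - p$r1)^2
  if (any(i3)) {
    s <- r[i3] - p$rbreak
    e[i3] <- w + fmax * s - fmax * s^2 / (2 * p$a)
  }
  e[i4] <- w + 0.5 * fmax * p$a
  e
}

#' Loading energy capacity of a breakable bond
#'
#' Closed-form energy a bond absorbs while loading from its equilibrium
#' length to its breaking distance:
#' `W = k0/2 (r1-r0)^2 + k0 (r1-r0)(rbreak-r1) + k1/2 (rbreak-r1)^2`.
#' This is the area under the restoring-force magnitude up to `rbreak`, and
#' the quantity (`W_AGE`, `W_TC`) entering the stiffening criterion.
#'
#' @param p A [trilinear_bond()] parameter object with finite `rbreak`.
#' @return Energy capacity W (kcal mol^-1).
#' @export
loading_energy_capacity <- function(p) {
  stopifnot(inherits(p, "trilinear_bond"))
  if (!is.finite(p$rbreak)) stop("rbreak is infinite; W undefined", call. = FALSE)
  d1 <- p$r1 - p$r0
  d2 <- p$rbreak - p$r1
  p$k0 / 2 * d1^2 + p$k0 * d1 * d2 + p$k1 / 2 * d2^2
}

#' Stiffening criterion ratio
#'
#' Ratio `N_AGE * W_AGE / W_TC` balancing the loading energy capacity of the
#' cross-links attached to one tropocollagen molecule against the capacity of
#' the molecule's own backbone. Values above 1 predict the
#' molecule-stretching-governed (stiffening) regime; the level set at 1 is
#' the theoretical boundary drawn in the stiffening phase maps.
#'
#' @param wtc Loading energy capacity of the backbone path (kcal mol^-1), > 0.
#' @param n_age Cross-links per tropocollagen molecule, >= 0.
#' @param wage Loading energy capacity of one cross-link (kcal mol^-1).
#' @return Dimensionless ratio.
#' @export
stiffening_ratio <- function(wtc, n_age, wage) {
  stopifnot(is.numeric(wtc), is.numeric(n_age), is.numeric(wage))
  if (any(wtc <= 0)) stop("wtc must be > 0", call. = FALSE)
  if (any(n_age < 0)) stop("n_age must be >= 0", call. = FALSE)
  n_age * wage / wtc
}

#' Nonbonded pair interaction parameters
#'
#' 12-6 pair potential representing dispersive (van der Waals like)
#' interactions between beads of distinct molecules, with the potential
#' energy shifted to zero at the cutoff. Directly bonded pairs and
#' second-neighbour (1-3) pairs along a chain are excluded by the engine.
#'
#' @param sigma Dispersive length parameter (Å); default 14.72.
#' @param epsilon Well depth (kcal mol^-1); default 6.87.
#' @param cutoff Interaction cutoff (Å); default `2.5 * sigma`.
#' @return An object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(sigma = 14.72, epsilon = 6.87,
                             cutoff = 2.5 * sigma) {
  stopifnot(sigma > 0, epsilon >= 0, cutoff >= sigma)
  structure(list(sigma = sigma, epsilon = epsilon, cutoff = cutoff),
            class = "nonbonded_params")
}

#' Nonbonded pair force and energy
#'
#' `pair_force()` returns the signed radial force (negative = attractive) of
#' the 12-6 potential; `pair_energy()` the cutoff-shifted energy. Both vanish
#' at and beyond the cutoff; the force vanishes at the potential minimum
#' `2^(1/6) sigma`.
#'
#' @param p A [nonbonded_params()] object.
#' @param r Distance(s), Å, > 0.
#' @return Force (kcal mol^-1 Å^-1) or energy (kcal mol^-1).
#' @export
pair_force <- function(p, r) {
  stopifnot(inherits(p, "nonbonded_params"), all(r > 0))
  sr6 <- (p$sigma / r)^6
  f <- -24 * p$epsilon * (2 * sr6^2 - sr6) / r
  f[r >= p$cutoff] <- 0
  # sign: positive sr12 term dominates at short range -> repulsive (positive)
  -f
}

#' @rdname pair_force
#' @export
pair_energy <- function(p, r) {
  stopifnot(inherits(p, "nonbonded_params"), all(r > 0))
  lj <- function(x) {
    sr6 <- (p$sigma / x)^6
    4 * p$epsilon * (sr6^2 - sr6)
  }
  e <- lj(r) - lj(p$cutoff)
  e[r >= p$cutoff] <- 0
  e
}

#' Harmonic angle parameters
#'
#' Bending potential `E = k_theta (theta - theta0)^2` applied to consecutive
#' backbone triplets, penalising molecular curvature.
#'
#' @param k_theta Bending stiffness (kcal mol^-1 rad^-2); default 14.98.
#' @param theta0 Equilibrium angle (rad); default `pi` (straight chain).
#' @return An object of class `angle_params`.
#' @export
angle_params <- function(k_theta = 14.98, theta0 = pi) {
  stopifnot(k_theta >= 0, theta0 > 0, theta0 <= pi)
  structure(list(k_theta = k_theta, theta0 = theta0), class = "angle_params")
}

#' Harmonic angle energy and generalized force
#'
#' `angle_energy()` evaluates `k_theta (theta - theta0)^2`;
#' `angle_torque()` its negative derivative `-2 k_theta (theta - theta0)`,
#' which vanishes at the equilibrium angle.
#'
#' @param p An [angle_params()] object.
#' @param theta Angle(s), rad.
#' @return Energy (kcal mol^-1) or torque (kcal mol^-1 rad^-1).
#' @export
angle_energy <- function(p, theta) {
  stopifnot(inherits(p, "angle_params"))
  p$k_theta * (theta - p$theta0)^2
}

#' @rdname angle_energy
#' @export
angle_torque <- function(p, theta) {
  stopifnot(inherits(p, "angle_params"))
  -2 * p$k_theta * (theta - p$theta0)
}

#' Assemble a force field
#'
#' Bundles the bonded, nonbonded and angular interaction parameters plus the
#' uniform bead mass into a single object consumed by the tensile-test
#' engine. All energies are kcal mol^-1, lengths Å, times fs, masses g mol^-1
#' (the "real"-units convention of mesoscale MD codes).
#'
#' @param collagen_bond Backbone bond, a [trilinear_bond()].
#' @param age_bond Cross-link bond, a [trilinear_bond()].
#' @param end_bond Grip-region bond; must be unbreakable (`rbreak = Inf`).
#' @param nonbonded A [nonbonded_params()] object.
#' @param angle An [angle_params()] object.
#' @param mass Uniform bead mass (g mol^-1). The default corresponds to the
#'   molecular weight of a tropocollagen molecule shared over its beads; the
#'   resulting backbone vibration period (~1 ps) is far above the 1 fs
#'   timestep.
#' @return An object of class `force_field`.
#' @examples
#' ff <- force_field(age_bond = age_bond(k1 = 12, rbreak = 35))
#' @export
force_field <- function(collagen_bond = fibrilmech::collagen_bond(),
                        age_bond = glucosepane_bond(),
                        end_bond = fibrilmech::end_bond(),
                        nonbonded = nonbonded_params(),
                        angle = angle_params(),
                        mass = 1358) {
  stopifnot(inherits(collagen_bond, "trilinear_bond"),
            inherits(age_bond, "trilinear_bond"),
            inherits(end_bond, "trilinear_bond"),
            inherits(nonbonded, "nonbonded_params"),
            inherits(angle, "angle_params"),
            mass > 0)
  if (is.finite(end_bond$rbreak)) {
    stop("end_bond must be unbreakable (rbreak = Inf)", call. = FALSE)
  }
  structure(list(collagen_bond = collagen_bond, age_bond = age_bond,
                 end_bond = end_bond, nonbonded = nonbonded, angle = angle,
                 mass = mass),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("<force_field>\n  backbone: ")
  print(x$collagen_bond)
  cat("  cross-link: ")
  print(x$age_bond)
  cat(sprintf("  pair: sigma=%.4g eps=%.3g cutoff=%.4g | angle k=%.3g | mass=%.4g\n",
              x$nonbonded$sigma, x$nonbonded$epsilon, x$nonbonded$cutoff,
              x$angle$k_theta, x$mass))
  invisible(x)
}
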