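#' Fibril geometry configuration
#'
#' Describes the D-periodic staggered bead-chain fibril before cross-link
#' insertion. Tropocollagen molecules are straight, axis-aligned chains of
#' equidistant beads packed on a two-dimensional triangular lattice; adjacent
#' lattice sites differ in axial phase (classic 5-staggered arrangement), and
#' along each lattice line molecules tile with an intra-line gap of
#' `gap_fraction * d_period`, producing the characteristic gap/overlap
#' banding with axial period `d_period`.
#'
#' @param d_period Axial D-period (Å); default 670.
#' @param gap_fraction Fraction of the D-period occupied by the gap zone;
#'   default 0.6.
#' @param particle_spacing Equilibrium bead spacing along a chain (Å);
#'   default 14.0.
#' @param n_particles_per_chain Beads per molecule (before end extension);
#'   default 218, giving a contour length of about 300 nm.
#' @param n_chains Number of lattice sites (molecules per cross-section);
#'   default 155. Ignored when `diameter` is given.
#' @param diameter Optional target cross-section diameter (Å); if supplied,
#'   all lattice sites within `diameter / 2` of the axis are used.
#' @param lattice_spacing Triangular-lattice spacing (Å). The default is the
#'   minimum of the 12-6 pair potential, `2^(1/6) * 14.72`, so the
#'   cross-section starts stress-free.
#' @param end_extension_particles Strengthened beads appended per extended
#'   chain end; default 40. A chain end is extended when it lies within
#'   `end_extension_particles * particle_spacing` of the global axial
#'   extremes of the fibril.
#' @param n_periods Molecules tiled per lattice line; default 2 (one fully
#'   developed banding period in the interior). Mechanical presets use 1,
#'   the representative specimen of the tensile tests.
#' @param n_stagger Number of stagger phases; default 5.
#' @param scale_factor Desk-scale shrink factor applied to the bead counts
#'   and the D-period (spacing and gap fraction preserved); default 1.
#' @return An object of class `fibril_config`.
#' @seealso [build_fibril()], [fibril_preset()]
#' @export
fibril_config <- function(d_period = 670,
                          gap_fraction = 0.6,
                          particle_spacing = 14.0,
                          n_particles_per_chain = 218,
                          n_chains = 155,
                          diameter = NULL,
                          lattice_spacing = 2^(1 / 6) * 14.72,
                          end_extension_particles = 40,
                          n_periods = 2,
                          n_stagger = 5,
                          scale_factor = 1) {
  stopifnot(d_period > 0, gap_fraction > 0, gap_fraction < 1,
            particle_spacing > 0, n_particles_per_chain >= 2,
            lattice_spacing > 0, end_extension_particles >= 0,
            n_periods >= 1, n_stagger >= 1,
            scale_factor > 0, scale_factor <= 1)
  if (is.null(diameter) && n_chains < 2) {
    stop("need at least 2 chains in the cross-section", call. = FALSE)
  }
  if (scale_factor < 1) {
    n_particles_per_chain <- max(3, round(n_particles_per_chain * scale_factor))
    end_extension_particles <- max(2, round(end_extension_particles * scale_factor))
    d_period <- d_period * scale_factor
  }
  structure(
    list(d_period = d_period, gap_fraction = gap_fraction,
         particle_spacing = particle_spacing,
         n_particles_per_chain = n_particles_per_chain,
         n_chains = n_chains, diameter = diameter,
         lattice_spacing = lattice_spacing,
         end_extension_particles = end_extension_particles,
         n_periods = n_periods, n_stagger = n_stagger,
         scale_factor = scale_factor),
    class = "fibril_config"
  )
}

#' Named fibril presets
#'
#' * `"default"` — 155-molecule cross-section, two tiling periods: the
#'   geometry showcase used for banding-period and gap-fraction checks.
#' * `"full"` — 155 molecules, one tiling period: the representative tensile
#'   specimen at full scale.
#' * `"reduced"` — 19-molecule cross-section, one period, full-length chains:
#'   the desk-scale specimen used for the stochastic tensile analyses.
#' * `"mini"` — 19 molecules at `scale_factor = 0.25`: the specimen used for
#'   parameter sweeps, where many tensile tests are needed.
#'
#' @param name Preset name.
#' @return A [fibril_config()].
#' @export
fibril_preset <- function(name = c("default", "full", "reduced", "mini")) {
  name <- match.arg(name)
  switch(name,
    default = fibril_config(),
    full    = fibril_config(n_periods = 1),
    reduced = fibril_config(n_chains = 19, n_periods = 1),
    mini    = fibril_config(n_chains = 19, n_periods = 1, scale_factor = 0.25)
  )
}

# triangular lattice sites for the cross-section, ordered (row, col), with
# round-robin stagger phases
.lattice_sites <- function(cfg) {
  a <- cfg$lattice_spacing
  n_target <- if (is.null(cfg$diameter)) cfg$n_chains else NULL
  r_max <- if (is.null(n_target)) cfg$diameter / 2 else
    a * (sqrt(n_target / pi / (sqrt(3) / 2)) + 2)
  nr <- ceiling(r_max / (a * sqrt(3) / 2)) + 1
  grid <- expand.grid(i = -(nr + 1):(nr + 1), j = -nr:nr)
  x <- (grid$i + (grid$j %% 2) / 2) * a
  y <- grid$j * a * sqrt(3) / 2
  sites <- tibble::tibble(i = grid$i, j = grid$j, x = x, y = y,
                          r = sqrt(x^2 + y^2))
  if (is.null(n_target)) {
    sites <- dplyr::filter(sites, r <= cfg$diameter / 2)
    if (nrow(sites) < 2) {
      stop("diameter too small for at least 2 chains", call. = FALSE)
    }
  } else {
    sites <- dplyr::slice_min(sites, order_by = r, n = n_target,
                              with_ties = FALSE)
  }
  sites <- dplyr::arrange(sites, j, i)
  sites$site <- seq_len(nrow(sites))
  sites$phase <- (sites$site - 1L) %% cfg$n_stagger
  sites
}

#' Build a staggered collagen fibril model
#'
#' Constructs particle coordinates, chain topology and bonded lists for the
#' configured fibril: straight chains on a triangular lattice, stagger offset
#' `phase * d_period` between phases, intra-line tiling period
#' `contour length + gap_fraction * d_period`, strengthened end extensions
#' where chains reach the fibril extremes, and grip particle sets at both
#' ends. Records the initial cross-section area `a0` (lattice area per site
#' times number of sites) and the nominal mean gap length `g_mean`.
#'
#' @param cfg A [fibril_config()].
#' @return An object of class `fibril_model`: a list with tibbles
#'   `particles` (id, chain, seq, kind, x, y, z), `bonds` (i, j, type),
#'   `chains`, integer grip id vectors in `grips`, and scalars `a0`,
#'   `g_mean`, `n_sites`, `n_molecules`, `l0`.
#' @examples
#' m <- build_fibril(fibril_config(n_chains = 7, n_particles_per_chain = 20,
#'                                 end_extension_particles = 4))
#' m
#' @export
build_fibril <- function(cfg) {
  stopifnot(inherits(cfg, "fibril_config"))
  sites <- .lattice_sites(cfg)
  np <- cfg$n_particles_per_chain
  sp <- cfg$particle_spacing
  L <- (np - 1) * sp
  gap <- cfg$gap_fraction * cfg$d_period
  P <- L + gap
  ext <- cfg$end_extension_particles
  ext_window <- ext * sp

  mols <- tidyr::expand_grid(sites, period = seq_len(cfg$n_periods) - 1L)
  mols$z_start <- mols$phase * cfg$d_period + mols$period * P
  mols$chain <- seq_len(nrow(mols))
  z_min <- min(mols$z_start)
  z_max <- max(mols$z_start + L)
  mols$ext_left <- ext > 0 & (mols$z_start - z_min) <= ext_window
  mols$ext_right <- ext > 0 & (z_max - (mols$z_start + L)) <= ext_window

  per_chain <- function(ch) {
    m <- mols[ch, ]
    z_body <- m$z_start + (0:(np - 1)) * sp
    kind <- rep("body", np)
    z <- z_body
    if (m$ext_left) {
      z <- c(m$z_start - (ext:1) * sp, z)
      kind <- c(rep("ext", ext), kind)
    }
    if (m$ext_right) {
      z <- c(z, m$z_start + L + (1:ext) * sp)
      kind <- c(kind, rep("ext", ext))
    }
    tibble::tibble(chain = m$chain, seq = seq_along(z), kind = kind,
                   x = m$x, y = m$y, z = z)
  }
  particles <- dplyr::bind_rows(lapply(seq_len(nrow(mols)), per_chain))
  particles$id <- seq_len(nrow(particles))
  particles <- particles[, c("id", "chain", "seq", "kind", "x", "y", "z")]

  # backbone bonds between consecutive beads; "end" type when either bead is
  # an extension bead
  nb <- nrow(particles)
  i <- particles$id[-nb]
  j <- particles$id[-1]
  same <- particles$chain[-nb] == particles$chain[-1]
  btype <- ifelse(particles$kind[-nb] == "ext" | particles$kind[-1] == "ext",
                  "end", "backbone")
  bonds <- tibble::tibble(i = i[same], j = j[same], type = btype[same])

  # grips: extension beads plus their anchoring terminal body bead, split by
  # fibril end
  left_ids <- integer(0); right_ids <- integer(0)
  for (ch in which(mols$ext_left | mols$ext_right)) {
    pc <- particles[particles$chain == ch, ]
    body_idx <- which(pc$kind == "body")
    if (mols$ext_left[ch]) {
      left_ids <- c(left_ids, pc$id[c(seq_len(min(body_idx) - 1), min(body_idx))])
    }
    if (mols$ext_right[ch]) {
      right_ids <- c(right_ids, pc$id[c(max(body_idx), seq(max(body_idx) + 1, nrow(pc)))])
    }
  }
  if (length(left_ids) == 0 || length(right_ids) == 0) {
    # no extensions configured: grip the terminal beads of extreme chains
    zr <- range(particles$z)
    left_ids <- particles$id[particles$z <= zr[1] + sp / 2]
    right_ids <- particles$id[particles$z >= zr[2] - sp / 2]
  }
  stopifnot(length(intersect(left_ids, right_ids)) == 0)

  a0 <- nrow(sites) * cfg$lattice_spacing^2 * sqrt(3) / 2
  structure(
    list(particles = particles, bonds = bonds,
         chains = tibble::as_tibble(mols[, c("chain", "site", "phase", "period",
                                             "z_start", "ext_left", "ext_right",
                                             "x", "y")]),
         grips = list(left = sort(unique(left_ids)),
                      right = sort(unique(right_ids))),
         config = cfg, a0 = a0, g_mean = gap,
         n_sites = nrow(sites), n_molecules = nrow(mols),
         n_body_bonds_per_chain = np - 1L,
         l0 = max(particles$z) - min(particles$z),
         n_age_target = 0L, n_age_inserted = 0L),
    class = "fibril_model"
  )
}

#' @export
print.fibril_model <- function(x, ...) {
  cat(sprintf(
    paste0("<fibril_model> %d particles, %d molecules (%d sites x %d periods)\n",
           "  D = %.4g A, gap = %.4g A, length = %.5g A, A0 = %.5g A^2\n",
           "  bonds: %d backbone, %d end, %d AGE cross-links\n"),
    nrow(x$particles), x$n_molecules, x$n_sites, x$config$n_periods,
    x$config$d_period, x$g_mean, x$l0, x$a0,
    sum(x$bonds$type == "backbone"), sum(x$bonds$type == "end"),
    sum(x$bonds$type == "age")))
  invisible(x)
}

#' Cross-link insertion specification
#'
#' @param n_age Target cross-link density, links per tropocollagen molecule
#'   (each link counted once); study values 0, 1, 2, 5, 10, 40.
#' @param central_fraction Fraction of each molecule's body beads eligible to
#'   carry a cross-link, centred on the molecule; default 0.95.
#' @param proximity_threshold Maximum distance (Å) between the two linked
#'   beads; default 20 (about one inter-molecular lateral spacing). The
#'   default admits side-by-side pairs of adjacent molecules only, so every
#'   inserted cross-link starts near its 18.52 Å equilibrium length and
#'   well inside its first force regime — bonds inserted close to their
#'   critical hyperelastic distance would make the initial fibril stiffness
#'   depend on the cross-link stiffness `k1`, which contradicts the
#'   cross-link-independent linear regime of the model.
#' @param seed RNG seed for the random placement.
#' @return An object of class `crosslink_spec`.
#' @export
crosslink_spec <- function(n_age, central_fraction = 0.95,
                           proximity_threshold = 20, seed = 1L) {
  stopifnot(n_age >= 0, central_fraction > 0, central_fraction <= 1,
            proximity_threshold > 0)
  structure(list(n_age = n_age, central_fraction = central_fraction,
                 proximity_threshold = proximity_threshold,
                 seed = as.integer(seed)),
            class = "crosslink_spec")
}

# all inter-chain bead pairs within `h` among the given particles, via cell
# hashing; returns tibble (i, j) with i < j, in a canonical order
.proximity_pairs <- function(pp, h) {
  key <- function(cx, cy, cz) paste(cx, cy, cz, sep = ",")
  pp$cx <- floor(pp$x / h); pp$cy <- floor(pp$y / h); pp$cz <- floor(pp$z / h)
  pp$cell <- key(pp$cx, pp$cy, pp$cz)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  out <- vector("list", nrow(offs))
  right <- pp[, c("id", "chain", "x", "y", "z", "cell")]
  names(right) <- c("id2", "chain2", "x2", "y2", "z2", "cell")
  for (k in seq_len(nrow(offs))) {
    lk <- pp
    lk$cell <- key(pp$cx + offs$dx[k], pp$cy + offs$dy[k], pp$cz + offs$dz[k])
    cand <- dplyr::inner_join(lk[, c("id", "chain", "x", "y", "z", "cell")],
                              right, by = "cell", relationship = "many-to-many")
    cand <- cand[cand$id < cand$id2 & cand$chain != cand$chain2, ]
    d2 <- (cand$x - cand$x2)^2 + (cand$y - cand$y2)^2 + (cand$z - cand$z2)^2
    cand <- cand[d2 <= h^2, c("id", "id2")]
    out[[k]] <- cand
  }
  pairs <- dplyr::distinct(dplyr::bind_rows(out))
  names(pairs) <- c("i", "j")
  dplyr::arrange(pairs, i, j)
}

#' Insert AGE cross-links into a fibril model
#'
#' Places `round(n_age * n_molecules)` cross-link bonds uniformly at random
#' among eligible bead pairs: both beads in the central `central_fraction` of
#' their molecule's body, on distinct molecules, within
#' `proximity_threshold`, and with at most one cross-link per bead. Placement
#' is deterministic for a fixed `(model, spec)` — in particular it does not
#' depend on any force-field parameter, so the same seed yields identical
#' cross-link locations across mechanical variants. If the eligible pairs are
#' exhausted before the target is reached a warning reports the achieved
#' density.
#'
#' `n_age` counts links per molecule of the model at its own scale. On
#' shortened molecules (`scale_factor < 1`) the same nominal density is a
#' proportionally higher linear density along the chain; analyses that
#' apply the stiffening energy balance therefore use the effective
#' full-length-equivalent density `n_age / scale_factor` (see
#' [run_sweep()], [phase_map()]).
#'
#' @param model A [build_fibril()] result.
#' @param spec A [crosslink_spec()].
#' @return The model with `"age"` bonds appended and `n_age_target`,
#'   `n_age_inserted` updated.
#' @export
insert_age_crosslinks <- function(model, spec) {
  stopifnot(inherits(model, "fibril_model"), inherits(spec, "crosslink_spec"))
  if (any(model$bonds$type == "age")) {
    stop("model already contains cross-links", call. = FALSE)
  }
  target <- as.integer(round(spec$n_age * model$n_molecules))
  model$n_age_target <- target
  if (target == 0L) return(model)

  np <- model$config$n_particles_per_chain
  margin <- floor(np * (1 - spec$central_fraction) / 2)
  body <- model$particles[model$particles$kind == "body", ]
  body <- dplyr::group_by(body, chain)
  body <- dplyr::mutate(body, bidx = dplyr::row_number())
  body <- dplyr::ungroup(body)
  elig <- body[body$bidx > margin & body$bidx <= np - margin, ]
  pairs <- .proximity_pairs(elig, spec$proximity_threshold)

  # reproducible local RNG
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  ord <- sample.int(nrow(pairs))

  used <- logical(max(model$particles$id))
  sel_i <- integer(target); sel_j <- integer(target)
  n_sel <- 0L
  for (k in ord) {
    a <- pairs$i[k]; b <- pairs$j[k]
    if (!used[a] && !used[b]) {
      used[a] <- TRUE; used[b] <- TRUE
      n_sel <- n_sel + 1L
      sel_i[n_sel] <- a; sel_j[n_sel] <- b
      if (n_sel == target) break
    }
  }
  if (n_sel < target) {
    warning(sprintf(
      "eligible pairs exhausted: inserted %d of %d cross-links (achieved density %.2f per molecule)",
      n_sel, target, n_sel / model$n_molecules), call. = FALSE)
  }
  new_bonds <- tibble::tibble(i = sel_i[seq_len(n_sel)],
                              j = sel_j[seq_len(n_sel)], type = "age")
  model$bonds <- dplyr::bind_rows(model$bonds, new_bonds)
  model$n_age_inserted <- n_sel
  model$crosslink_spec <- spec
  model
}

# centered moving average, ends padded by edge values
.movavg <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  xp <- c(rep(x[1], w), x, rep(x[n], w))
  k <- rep(1 / w, w)
  sm <- stats::filter(xp, k, sides = 2)
  as.numeric(sm[(w + 1):(w + n)])
}

#' Dominant axial density period
#'
#' Histograms the axial positions of the body beads (bin width `bin`, at
#' most 5 Å), smooths the counts over one bead spacing (removing the
#' discrete bead comb), removes the slowly varying envelope of the finite
#' specimen with a long moving average, autocorrelates the residual, and
#' returns the lag with maximal autocorrelation within `[0.5, 1.5]`
#' D-periods — the banding period of the built fibril.
#'
#' @param model A `fibril_model`.
#' @param bin Histogram bin width (Å), default 2 (must be <= 5).
#' @return Dominant period (Å).
#' @export
axial_density_period <- function(model, bin = 2) {
  stopifnot(inherits(model, "fibril_model"), bin > 0, bin <= 5)
  if (model$n_sites < 2) {
    stop("axial period undefined for a single-chain model", call. = FALSE)
  }
  z <- model$particles$z[model$particles$kind == "body"]
  breaks <- seq(min(z) - bin, max(z) + bin, by = bin)
  counts <- graphics::hist(z, breaks = breaks, plot = FALSE)$counts
  sm <- .movavg(counts, max(1L, round(model$config$particle_spacing / bin)))
  trend <- .movavg(sm, max(3L, round(1.5 * model$config$d_period / bin)))
  xc <- sm - trend
  d <- model$config$d_period
  lags <- seq.int(max(1L, floor(0.5 * d / bin)), ceiling(1.5 * d / bin))
  n <- length(xc)
  ac <- vapply(lags, function(l) sum(xc[1:(n - l)] * xc[(1 + l):n]), 0)
  if (all(ac <= 0)) {
    stop("no secondary density peak found in the search window", call. = FALSE)
  }
  lags[which.max(ac)] * bin
}

#' Measured gap fraction of the banding pattern
#'
#' Fraction of axial bins at low bead density within a fully tiled interior
#' window (one complete tiling period starting where all lattice lines have
#' begun). Bins are classified low when their count is below the midpoint of
#' the window's minimum and maximum. Requires at least two tiling periods.
#'
#' @inheritParams axial_density_period
#' @return Fraction in (0, 1).
#' @export
gap_fraction_measured <- function(model, bin = 5) {
  stopifnot(inherits(model, "fibril_model"))
  cfg <- model$config
  if (cfg$n_periods < 2) {
    stop("gap fraction measurement needs n_periods >= 2", call. = FALSE)
  }
  L <- (cfg$n_particles_per_chain - 1) * cfg$particle_spacing
  P <- L + model$g_mean
  w0 <- (cfg$n_stagger - 1) * cfg$d_period
  stopifnot(w0 + P <= max(model$particles$z))
  # per-bin molecular coverage: number of molecules whose body span covers
  # the bin centre (equivalent to the bead histogram with the bead comb
  # integrated out)
  mids <- seq(w0 + bin / 2, w0 + P - bin / 2, by = bin)
  cov <- numeric(length(mids))
  for (ch in seq_len(nrow(model$chains))) {
    z0 <- model$chains$z_start[ch]
    cov <- cov + (mids >= z0 & mids <= z0 + L)
  }
  thr <- (max(cov) + min(cov)) / 2
  mean(cov < thr)
}
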