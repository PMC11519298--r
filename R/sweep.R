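#' Parameter-sweep specification
#'
#' The sweep design of the study: cross-link stiffness `k1` and breaking
#' distance `rbreak` grids, cross-link densities `n_age`, a geometry preset
#' and replicate seeds. The glucosepane reference point (k1 = 8,
#' rbreak = 31.72) can be appended, and a zero-density reference is always
#' included (it provides the normalization energies).
#'
#' @param k1 Cross-link stiffness values (kcal mol^-1 Å^-2).
#' @param rbreak Cross-link breaking distances (Å).
#' @param n_age Cross-link densities (links per molecule).
#' @param preset Geometry preset name, see [fibril_preset()]; sweeps default
#'   to `"mini"` because each cell is a full destructive test.
#' @param seeds Replicate seeds (placement and thermostat).
#' @param include_glucosepane Append the glucosepane (8, 31.72) cell.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(k1 = c(6, 8, 12, 16, 24),
                       rbreak = c(25, 27, 30, 33, 35, 40, 50, 60),
                       n_age = c(0, 1, 2, 5, 10, 40),
                       preset = "mini", seeds = 1L,
                       include_glucosepane = TRUE) {
  stopifnot(length(k1) >= 1, length(rbreak) >= 1, length(n_age) >= 1,
            length(seeds) >= 1)
  if (!0 %in% n_age) n_age <- c(0, n_age)
  structure(list(k1 = k1, rbreak = rbreak, n_age = sort(unique(n_age)),
                 preset = preset, seeds = as.integer(seeds),
                 include_glucosepane = isTRUE(include_glucosepane)),
            class = "sweep_spec")
}

.sweep_cells <- function(spec) {
  grid <- tidyr::expand_grid(k1 = spec$k1, rbreak = spec$rbreak)
  if (spec$include_glucosepane &&
      !any(grid$k1 == 8 & grid$rbreak == 31.72)) {
    grid <- dplyr::bind_rows(grid, tibble::tibble(k1 = 8, rbreak = 31.72))
  }
  grid
}

.cell_key <- function(preset, seed, n_age, k1, rbreak) {
  if (n_age == 0) sprintf("%s_s%d_n0", preset, seed)
  else sprintf("%s_s%d_n%g_k1%g_rb%g", preset, seed, n_age, k1, rbreak)
}

.run_config_json <- function(model_cfg, protocol, ff, age, n_age, seed) {
  jsonlite::toJSON(list(geometry = unclass(model_cfg),
                        protocol = unclass(protocol),
                        collagen = unclass(ff$collagen_bond),
                        nonbonded = unclass(ff$nonbonded),
                        angle = unclass(ff$angle), mass = ff$mass,
                        age = unclass(age), n_age = n_age, seed = seed),
                   auto_unbox = TRUE, digits = NA)
}

#' Run a tensile-test parameter sweep
#'
#' Executes one destructive tensile test per sweep cell. For a given
#' `(n_age, seed)` the cross-link placement is generated once and reused
#' across every `(k1, rbreak)` cell, separating deterministic from
#' statistical effects. Each seed's zero-density reference run supplies the
#' energy normalizations. When `out_dir` is given, per-run metrics are
#' cached as JSON keyed by the full run configuration and reused on
#' identical re-runs; cell failures are recorded in the `status` column and
#' the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param out_dir Optional cache/output directory.
#' @param ff_base Force field providing everything except the cross-link
#'   bond, which the sweep varies.
#' @param protocol Tensile protocol; the default pulls to strain 0.5 with
#'   post-failure stress-collapse termination so broken-bond censuses are
#'   taken after failure.
#' @param quiet Suppress progress messages.
#' @return A tibble (class `fibril_sweep`), one row per run: parameters,
#'   `wage`, the energy-balance `ratio`, all [fibril_metrics()] columns,
#'   normalized energies and `status`. Attribute `wtc` carries the backbone
#'   capacity used by [phase_map()].
#' @export
run_sweep <- function(spec, out_dir = NULL, ff_base = force_field(),
                      protocol = protocol_preset("desk", strain_limit = 0.5,
                                                 collapse_frac = 0.25),
                      quiet = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  base_model <- build_fibril(fibril_preset(spec$preset))
  wtc <- loading_energy_capacity(ff_base$collagen_bond)
  grid <- .sweep_cells(spec)
  rows <- list()

  one_run <- function(model, ff, seed, key, cfg_json, reference) {
    cache_file <- if (!is.null(out_dir)) file.path(out_dir, paste0(key, ".json"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      cached <- jsonlite::fromJSON(cache_file, simplifyVector = TRUE)
      if (identical(as.character(cached$config), as.character(cfg_json))) {
        say("cache hit: %s", key)
        return(list(metrics = tibble::as_tibble(cached$metrics), cached = TRUE))
      }
    }
    run <- run_tension(model, ff, protocol, seed = seed)
    met <- fibril_metrics(run, reference = reference)
    if (!is.null(cache_file)) {
      jsonlite::write_json(list(config = cfg_json, metrics = as.list(met)),
                           cache_file, auto_unbox = TRUE, digits = NA)
    }
    list(metrics = met, cached = FALSE)
  }

  for (seed in spec$seeds) {
    # zero-density reference
    key0 <- .cell_key(spec$preset, seed, 0, NA, NA)
    cfg0 <- .run_config_json(base_model$config, protocol, ff_base,
                             list(reference = TRUE), 0, seed)
    say("reference run (n_age = 0, seed %d)", seed)
    ref <- tryCatch(one_run(base_model, ff_base, seed, key0, cfg0, NULL),
                    error = function(e) e)
    if (inherits(ref, "error")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        preset = spec$preset, seed = seed, n_age = 0, k1 = NA_real_,
        rbreak = NA_real_, status = conditionMessage(ref))
      next
    }
    refm <- ref$metrics
    refm$e_stretch_norm <- 1
    refm$e_slide_norm <- 1
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(preset = spec$preset, seed = seed, n_age = 0,
                     n_age_eff = 0, k1 = NA_real_, rbreak = NA_real_,
                     wage = NA_real_, ratio = 0),
      refm, tibble::tibble(status = "ok"))

    for (na in setdiff(spec$n_age, 0)) {
      model_n <- suppressWarnings(
        insert_age_crosslinks(base_model, crosslink_spec(na, seed = seed)))
      for (g in seq_len(nrow(grid))) {
        k1 <- grid$k1[g]; rb <- grid$rbreak[g]
        age <- age_bond(k1, rb)
        ff <- force_field(collagen_bond = ff_base$collagen_bond,
                          age_bond = age, end_bond = ff_base$end_bond,
                          nonbonded = ff_base$nonbonded,
                          angle = ff_base$angle, mass = ff_base$mass)
        key <- .cell_key(spec$preset, seed, na, k1, rb)
        cfg <- .run_config_json(base_model$config, protocol, ff, age, na, seed)
        say("run: n_age=%g k1=%g rbreak=%g seed=%d", na, k1, rb, seed)
        out <- tryCatch(one_run(model_n, ff, seed, key, cfg, refm),
                        error = function(e) e)
        if (inherits(out, "error")) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            preset = spec$preset, seed = seed, n_age = na, k1 = k1,
            rbreak = rb, status = conditionMessage(out))
          next
        }
        wage <- loading_energy_capacity(age)
        # effective full-length-equivalent density: the energy balance is a
        # linear-density criterion, so shortened molecules count their
        # links relative to the full-length molecule
        na_eff <- na / base_model$config$scale_factor
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(preset = spec$preset, seed = seed, n_age = na,
                         n_age_eff = na_eff, k1 = k1, rbreak = rb,
                         wage = wage,
                         ratio = stiffening_ratio(wtc, na_eff, wage)),
          out$metrics, tibble::tibble(status = "ok"))
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
  }
  attr(res, "wtc") <- wtc
  class(res) <- c("fibril_sweep", class(res))
  res
}
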