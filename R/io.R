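#' Write a fibril model as a LAMMPS data file
#'
#' Serializes the model in the `atom_style molecular` dialect (header
#' counts, Masses, Atoms, Bonds, Angles sections; 1-based indices; atom
#' types 1 = body bead, 2 = extension bead; bond types 1 = backbone,
#' 2 = end-strengthened, 3 = AGE cross-link). Model metadata that the data
#' format cannot carry (configuration, grips, chain table, derived scalars)
#' is stored as a JSON payload on the title line, so that
#' [load_model()] round-trips losslessly.
#'
#' @param model A `fibril_model`.
#' @param path Output file path.
#' @param mass Bead mass written to the Masses section (g mol^-1).
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(model, path, mass = 1358) {
  stopifnot(inherits(model, "fibril_model"))
  p <- model$particles
  if (nrow(p) == 0) stop("empty model", call. = FALSE)
  b <- model$bonds
  ang <- .angle_triplets(model)
  meta <- list(
    config = unclass(model$config),
    grips = model$grips,
    chains = as.list(model$chains),
    a0 = model$a0, g_mean = model$g_mean, l0 = model$l0,
    n_sites = model$n_sites, n_molecules = model$n_molecules,
    n_body_bonds_per_chain = model$n_body_bonds_per_chain,
    n_age_target = model$n_age_target,
    n_age_inserted = model$n_age_inserted)
  meta_json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                null = "null")
  btype <- c(backbone = 1L, end = 2L, age = 3L)[b$type]
  atype <- ifelse(p$kind == "body", 1L, 2L)
  pad <- function(v) format(v, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste0("LAMMPS data file via fibrilmech | meta=", meta_json),
    "",
    paste(nrow(p), "atoms"),
    paste(nrow(b), "bonds"),
    paste(nrow(ang), "angles"),
    "2 atom types",
    "3 bond types",
    "1 angle types",
    "",
    sprintf("%.8f %.8f xlo xhi", min(p$x) - 50, max(p$x) + 50),
    sprintf("%.8f %.8f ylo yhi", min(p$y) - 50, max(p$y) + 50),
    sprintf("%.8f %.8f zlo zhi", min(p$z) - 50, max(p$z) + 50),
    "",
    "Masses",
    "",
    sprintf("1 %.8f", mass),
    sprintf("2 %.8f", mass),
    "",
    "Atoms # molecular",
    "",
    sprintf("%d %d %d %.8f %.8f %.8f", p$id, p$chain, atype, p$x, p$y, p$z),
    "",
    "Bonds",
    "",
    sprintf("%d %d %d %d", seq_len(nrow(b)), btype, b$i, b$j))
  if (nrow(ang) > 0) {
    lines <- c(lines, "", "Angles", "",
               sprintf("%d 1 %d %d %d", seq_len(nrow(ang)),
                       ang[, 1], ang[, 2], ang[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a fibril model from a LAMMPS data file
#'
#' Inverse of [write_lammps_data()]; requires the metadata payload written
#' by it. Malformed files raise an error naming the offending line.
#'
#' @param path File path.
#' @return A `fibril_model`.
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  fail <- function(ln, msg) {
    stop(sprintf("parse error at line %d of %s: %s", ln, path, msg),
         call. = FALSE)
  }
  if (length(lines) < 10) fail(length(lines), "file too short")
  m <- regmatches(lines[1], regexpr("meta=\\{.*\\}$", lines[1]))
  if (length(m) == 0) fail(1, "missing fibrilmech metadata payload")
  meta <- jsonlite::fromJSON(sub("^meta=", "", m), simplifyVector = TRUE)

  grab_count <- function(word) {
    i <- grep(paste0("^[0-9]+ ", word, "$"), lines)
    if (length(i) != 1) fail(1, paste("missing", word, "count"))
    as.integer(sub(paste0(" ", word), "", lines[i]))
  }
  n_atoms <- grab_count("atoms")
  n_bonds <- grab_count("bonds")
  n_angles <- grab_count("angles")

  section <- function(name, n, ncol_expect) {
    i <- which(lines == name | startsWith(lines, paste0(name, " #")))
    if (length(i) != 1) fail(1, paste("missing section", name))
    start <- i + 2
    if (start + n - 1 > length(lines)) fail(length(lines),
                                            paste("truncated section", name))
    block <- lines[start:(start + n - 1)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) != ncol_expect)
    if (length(bad) > 0) fail(start + bad[1] - 1,
                              paste("malformed record in", name))
    do.call(rbind, lapply(parts, as.numeric))
  }

  at <- section("Atoms", n_atoms, 6)
  bd <- section("Bonds", n_bonds, 4)
  if (n_angles > 0) section("Angles", n_angles, 5)  # validated, regenerated

  ord <- order(at[, 1])
  at <- at[ord, , drop = FALSE]
  particles <- tibble::tibble(
    id = as.integer(at[, 1]), chain = as.integer(at[, 2]),
    kind = ifelse(at[, 3] == 1, "body", "ext"),
    x = at[, 4], y = at[, 5], z = at[, 6])
  particles <- dplyr::group_by(particles, .data$chain)
  particles <- dplyr::mutate(particles, seq = dplyr::row_number())
  particles <- dplyr::ungroup(particles)
  particles <- particles[, c("id", "chain", "seq", "kind", "x", "y", "z")]

  bd <- bd[order(bd[, 1]), , drop = FALSE]
  bonds <- tibble::tibble(
    i = as.integer(bd[, 3]), j = as.integer(bd[, 4]),
    type = c("backbone", "end", "age")[bd[, 2]])

  cfg <- meta$config
  cfg$scale_factor <- 1  # counts already materialized; avoid re-scaling
  cfg_obj <- do.call(fibril_config, cfg[setdiff(names(cfg), "scale_factor")])
  cfg_obj$scale_factor <- meta$config$scale_factor

  structure(
    list(particles = particles, bonds = bonds,
         chains = tibble::as_tibble(meta$chains),
         grips = list(left = as.integer(meta$grips$left),
                      right = as.integer(meta$grips$right)),
         config = cfg_obj, a0 = meta$a0, g_mean = meta$g_mean,
         n_sites = meta$n_sites, n_molecules = meta$n_molecules,
         n_body_bonds_per_chain = meta$n_body_bonds_per_chain,
         l0 = meta$l0, n_age_target = meta$n_age_target,
         n_age_inserted = meta$n_age_inserted),
    class = "fibril_model")
}

#' Write particle coordinates as XYZ
#'
#' Visualization-only export: body beads as element `C`, extension beads as
#' `H`.
#'
#' @inheritParams write_lammps_data
#' @return `path`, invisibly.
#' @export
write_xyz <- function(model, path) {
  stopifnot(inherits(model, "fibril_model"))
  p <- model$particles
  if (nrow(p) == 0) stop("empty model", call. = FALSE)
  el <- ifelse(p$kind == "body", "C", "H")
  writeLines(c(
    as.character(nrow(p)),
    "fibrilmech model",
    sprintf("%s %.6f %.6f %.6f", el, p$x, p$y, p$z)), path)
  invisible(path)
}
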