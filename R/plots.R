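#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stress-strain curve of a tensile run
#'
#' @param object A `tension_run`.
#' @param smooth Moving-average window (records) for a smoothed overlay;
#'   0 disables.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tension_run
#' @export
autoplot.tension_run <- function(object, smooth = 5, ...) {
  s <- object$series
  g <- ggplot2::ggplot(s, ggplot2::aes(x = .data$strain, y = .data$sigma)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::labs(x = "engineering strain", y = "engineering stress (MPa)") +
    ggplot2::theme_minimal()
  if (smooth > 1) {
    s2 <- dplyr::mutate(s, sigma_s = .movavg(.data$sigma, smooth))
    g <- g + ggplot2::geom_line(data = s2,
                                ggplot2::aes(y = .data$sigma_s),
                                colour = "black", linewidth = 0.6)
  }
  g
}

#' Axial density profile of a fibril model
#'
#' Bead-count histogram along the fibril axis, showing the gap/overlap
#' banding.
#'
#' @param object A `fibril_model`.
#' @param bin Bin width (Å).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fibril_model
#' @export
autoplot.fibril_model <- function(object, bin = 5, ...) {
  z <- object$particles$z[object$particles$kind == "body"]
  ggplot2::ggplot(tibble::tibble(z = z), ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(binwidth = bin, boundary = 0, fill = "grey30") +
    ggplot2::labs(x = "axial position (Å)", y = "beads per bin") +
    ggplot2::theme_minimal()
}

#' Stiffening phase map plot
#'
#' Tile map of the elastic-to-peak stress difference over (k1, rbreak) per
#' cross-link density, with the theoretical energy-balance boundary
#' overlaid.
#'
#' @param object A [phase_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_map
#' @export
autoplot.phase_map <- function(object, ...) {
  cells <- dplyr::filter(object$cells, .data$n_age > 0)
  g <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$k1, y = .data$rbreak)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$delta_sigma)) +
    ggplot2::geom_point(data = dplyr::filter(cells, .data$observed),
                        shape = 8, size = 2) +
    ggplot2::facet_wrap(~n_age, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * sigma ~ "(MPa)")) +
    ggplot2::labs(x = expression(k[1] ~ "(kcal/mol/Å"^2 * ")"),
                  y = expression(r[break] ~ "(Å)")) +
    ggplot2::theme_minimal()
  bnd <- dplyr::filter(object$boundary, !is.na(.data$rbreak),
                       .data$rbreak <= max(cells$rbreak))
  if (nrow(bnd) > 0) {
    g <- g + ggplot2::geom_line(data = bnd, linetype = "dashed",
                                colour = "grey20")
  }
  g
}

#' Energy-partition summary plot
#'
#' Normalized sliding and stretching energies against the cross-link loading
#' energy capacity, per density — the saturating exchange between the
#' sliding and stretching failure mechanisms.
#'
#' @param results A `fibril_sweep` tibble (needs `wage`, `n_age`,
#'   `e_slide_norm`, `e_stretch_norm`).
#' @return A ggplot.
#' @export
plot_energy_partition <- function(results) {
  stopifnot(is.data.frame(results))
  d <- dplyr::filter(results, .data$n_age > 0, .data$status == "ok")
  d <- tidyr::pivot_longer(
    d[, c("wage", "n_age", "e_slide_norm", "e_stretch_norm")],
    cols = c("e_slide_norm", "e_stretch_norm"),
    names_to = "mechanism", values_to = "energy")
  d$mechanism <- ifelse(d$mechanism == "e_slide_norm",
                        "sliding E/E0", "stretching E/E0")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wage, y = .data$energy,
                                  colour = factor(.data$n_age))) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~mechanism, scales = "free_y") +
    ggplot2::labs(x = expression(W[AGE] ~ "(kcal/mol)"), y = NULL,
                  colour = expression(N[AGE])) +
    ggplot2::theme_minimal()
}
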