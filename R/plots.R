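# ggplot2 views: lattice snapshots colour-coded by adhesion preference
# (0 blue -> 7 red) and metric time courses for runs and ensembles.

adhesion_colours <- function() {
  grDevices::colorRampPalette(c("#2166AC", "#67A9CF", "#D1E5F0",
                                "#FDDBC7", "#EF8A62", "#B2182B"))(8)
}

#' @describeIn plot_spheroid autoplot method for `tumour_state`.
#' @param object,x a `tumour_state`, `spheroid_sim` or `spheroid_ensemble`.
#' @param ... unused.
#' @export
autoplot.tumour_state <- function(object, ...) plot_spheroid(object, ...)

#' Plot a spheroid snapshot
#'
#' Tile plot of the occupancy grid, coloured by adhesion preference from 0
#' (blue, low adhesive) to 7 (red, highly adhesive), cropped to the occupied
#' region.
#'
#' @param state a `tumour_state`.
#' @param pad margin of empty sites kept around the tumour.
#' @return a ggplot.
#' @export
plot_spheroid <- function(state, pad = 5) {
  lc <- live_cells(state)
  if (nrow(lc) == 0) abort("nothing to plot: no live cells")
  lim_i <- range(lc$i) + c(-pad, pad)
  lim_j <- range(lc$j) + c(-pad, pad)
  lc$adhesion <- factor(lc$phenotype, levels = 0:7)
  ggplot2::ggplot(lc, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$adhesion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = adhesion_colours(), drop = FALSE,
                               name = "adhesion\npreference") +
    ggplot2::coord_fixed(xlim = lim_j, ylim = lim_i) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("t = %g h, %d cells", state$time_h,
                                  nrow(lc))) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_spheroid metric time courses of a single run.
#' @param metrics metric columns to show.
#' @export
autoplot.spheroid_sim <- function(object,
                                  metrics = c("n_cells",
                                              "invasive_radius_um",
                                              "core_radius_um",
                                              "compactness", "sparseness"),
                                  ...) {
  df <- tidy(object) |> filter(.data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_spheroid ensemble mean +/- SD ribbons.
#' @export
autoplot.spheroid_ensemble <- function(object,
                                       metrics = c("n_cells",
                                                   "invasive_radius_um",
                                                   "compactness",
                                                   "sparseness"),
                                       ...) {
  df <- tidy(object) |> filter(.data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_spheroid oxygen concentration heat map.
#' @export
autoplot.oxygen_field <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object$grid)),
                           j = seq_len(ncol(object$grid)))
  df$o <- as.vector(object$grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$o)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "oxygen") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
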