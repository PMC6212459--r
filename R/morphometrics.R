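# Morphometrics of occupancy grids and metric time series, mirroring the
# image-analysis quantities used for the in vitro spheroids: core and
# invasive radii, local compactness, local sparseness, phenotype frequencies
# and regression-based expansion speeds.

#' Invasive radius
#'
#' The maximum radius, taken from the initial-disc centre, that encloses all
#' live cells (in micrometres). The fixed centre (rather than the evolving
#' centroid) keeps the metric stable under asymmetric invasion.
#'
#' @param state a `tumour_state`.
#' @return radius in um; `NA` for an empty tumour.
#' @export
invasive_radius <- function(state) {
  lc <- live_cells(state)
  if (nrow(lc) == 0) return(NA_real_)
  max(lc$dist_um)
}

#' Core (maternal spheroid) radius
#'
#' For the U87MG-like morphology the maternal core is the 8-connected cell
#' component containing the centre-most cell; its radius is the maximum
#' centre distance within that component. For the primary-like morphology the
#' core cannot be separated from the invasive area (the phenotypes are
#' spatially mixed), so the metric is reported as missing.
#'
#' @param state a `tumour_state`.
#' @param cell_line `"u87mg"` or `"primary"`.
#' @return radius in um; `NA` when not applicable or the tumour is empty.
#' @export
core_radius <- function(state, cell_line = c("u87mg", "primary")) {
  cell_line <- arg_match(cell_line)
  if (identical(cell_line, "primary")) return(NA_real_)
  lc <- live_cells(state)
  if (nrow(lc) == 0) return(NA_real_)
  comp <- cpp_label_components(state$occ)
  centre_cell <- lc[which.min(lc$dist_um), ]
  lab <- comp$labels[centre_cell$i, centre_cell$j]
  in_core <- comp$labels[cbind(lc$i, lc$j)] == lab
  max(lc$dist_um[in_core])
}

#' Local compactness
#'
#' Mean over live cells of the occupied Moore-neighbour fraction (count / 8,
#' truncated at borders): 0 for fully isolated cells, approaching 1 for a
#' large packed disc.
#'
#' @param state a `tumour_state`.
#' @return value in `[0, 1]`; `NA` for an empty tumour.
#' @export
compactness <- function(state) cpp_compactness(state$occ)

#' Local sparseness
#'
#' Mean over live cells of the distance to the nearest other cell, in units
#' of the site size `h`: 1.0 for a perfectly packed configuration, growing as
#' cells spread apart.
#'
#' @param state a `tumour_state`.
#' @return dimensionless value `>= 1`; `NA` with fewer than two live cells.
#' @export
sparseness <- function(state) cpp_sparseness(state$occ)

#' Fraction of cells in the largest connected component
#'
#' An 8-connectivity cohesion measure: near 1 for the sheet-like primary
#' morphology, well below 1 for the starburst U87MG morphology whose invasive
#' cells scatter as singletons.
#'
#' @param state a `tumour_state`.
#' @return fraction in `(0, 1]`; `NA` for an empty tumour.
#' @export
largest_component_fraction <- function(state) {
  comp <- cpp_label_components(state$occ)
  if (length(comp$sizes) == 0) return(NA_real_)
  max(comp$sizes) / sum(comp$sizes)
}

#' Phenotype frequencies
#'
#' @param state a `tumour_state`.
#' @return named numeric vector of relative frequencies of adhesion values
#'   0--7 among live cells (sums to 1).
#' @export
phenotype_frequencies <- function(state) {
  lc <- live_cells(state)
  if (nrow(lc) == 0) abort("no live cells")
  tab <- tabulate(lc$phenotype + 1L, nbins = 8)
  setNames(tab / sum(tab), paste0("freq_", 0:7))
}

#' All morphometrics of a state as one tibble row
#'
#' @param state a `tumour_state`.
#' @param cell_line passed to [core_radius()].
#' @return one-row tibble with cell count, radii, rim, compactness,
#'   sparseness, largest-component fraction and phenotype frequencies.
#' @export
morphology_metrics <- function(state, cell_line = c("u87mg", "primary")) {
  cell_line <- arg_match(cell_line)
  core <- core_radius(state, cell_line)
  inv <- invasive_radius(state)
  base <- tibble(time_h = state$time_h, n_cells = sum(state$cells$alive),
                 invasive_radius_um = inv, core_radius_um = core,
                 invasive_rim_um = inv - core,
                 largest_cc_frac = largest_component_fraction(state),
                 compactness = compactness(state),
                 sparseness = sparseness(state))
  bind_cols(base, as_tibble(as.list(phenotype_frequencies(state))))
}

#' Expansion speed by linear regression
#'
#' Ordinary-least-squares slope of a radius metric against time, restricted
#' to a window -- the regression-based expansion speed used to compare the
#' simulated and in vitro kinetics. Applied to an ensemble, the slope is
#' fitted to the per-timepoint ensemble mean.
#'
#' @param x a metrics tibble (with a `time_h` column), a `spheroid_sim`, or a
#'   `spheroid_ensemble`.
#' @param window `c(t0, t1)` in hours (inclusive).
#' @param metric metric column to regress, e.g. `"invasive_radius_um"`.
#' @return slope in um/h.
#' @seealso [fit_expansion()] for the full regression object.
#' @export
expansion_speed <- function(x, window = c(24, 96),
                            metric = "invasive_radius_um") {
  unname(coef(fit_expansion(x, window, metric)$fit)[2])
}

#' @rdname expansion_speed
#' @return `fit_expansion()` returns an `expansion_fit` holding the `lm` fit,
#'   the window and the metric; see [tidy.expansion_fit()].
#' @export
fit_expansion <- function(x, window = c(24, 96),
                          metric = "invasive_radius_um") {
  df <- expansion_series(x, metric)
  df <- filter(df, .data$time_h >= window[1] - 1e-9,
               .data$time_h <= window[2] + 1e-9, !is.na(.data$value))
  if (nrow(df) < 2) abort("fewer than 2 timepoints in the regression window")
  fit <- lm(value ~ time_h, data = df)
  structure(list(fit = fit, window = window, metric = metric,
                 n_points = nrow(df)),
            class = "expansion_fit")
}

expansion_series <- function(x, metric) {
  if (inherits(x, "spheroid_sim")) x <- x$metrics
  if (inherits(x, "spheroid_ensemble")) {
    col <- paste0(metric, "_mean")
    if (!col %in% names(x$summary)) abort(sprintf("no column `%s`", col))
    return(tibble(time_h = x$summary$time_h, value = x$summary[[col]]))
  }
  if (!is.data.frame(x) || !all(c("time_h", metric) %in% names(x))) {
    abort("`x` must contain `time_h` and the metric column")
  }
  tibble(time_h = x$time_h, value = x[[metric]])
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("<expansion_fit> %s over [%g, %g] h: %.3g um/h (n = %d)\n",
              x$metric, x$window[1], x$window[2],
              coef(x$fit)[2], x$n_points))
  invisible(x)
}
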