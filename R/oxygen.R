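# Oxygen reaction-diffusion field on the lattice:
#   do/dt = D_o lap(o) - gamma_o o c_ij - alpha_o o
# with Dirichlet boundaries held at o_max (the culture medium). Live cells
# (c_ij = 1) consume oxygen; cells die where o < o_deadly.

#' Create an oxygen field
#'
#' @param geometry a [lattice_geometry()], or `NULL` when `dim` is given.
#' @param params an [oxygen_params()].
#' @param dim optional `c(nr, nc)` for non-square test grids.
#' @param value initial concentration everywhere (defaults to `o_max`).
#' @return an `oxygen_field`: list with the concentration `grid`, `params`
#'   and site size `h_um`.
#' @export
oxygen_field <- function(geometry = lattice_geometry(),
                         params = oxygen_params(),
                         dim = NULL, value = params$o_max) {
  if (is.null(dim)) dim <- c(geometry$n, geometry$n)
  h_um <- if (is.null(geometry)) 20 else geometry$h_um
  structure(list(grid = matrix(value, dim[1], dim[2]),
                 params = params, h_um = h_um),
            class = "oxygen_field")
}

#' Advance the oxygen field in time
#'
#' Explicit finite-difference integration (5-point Laplacian) of the oxygen
#' equation over `duration_h` hours. The substep is chosen internally as
#' `min(duration, 0.9 h^2 / (4 D_o))` (plus a positivity bound on the reaction
#' term), which guarantees the discrete maximum principle: the field stays in
#' `[0, o_max]`. Boundary sites are held at `o_max` after every substep.
#'
#' @param field an `oxygen_field`.
#' @param occupancy integer matrix of the same dimensions; entries `> 0` mark
#'   sites occupied by live, oxygen-consuming cells. A `tumour_state` may be
#'   passed instead.
#' @param duration_h time to advance, in hours.
#' @param boundary `"dirichlet"` clamps all four edges at `o_max`;
#'   `"reflect_rows"` mirrors the first/last rows (zero flux) so a thin strip
#'   behaves as a 1D problem between its Dirichlet columns.
#' @return the advanced `oxygen_field`.
#' @export
oxygen_advance <- function(field, occupancy, duration_h,
                           boundary = c("dirichlet", "reflect_rows")) {
  boundary <- arg_match(boundary)
  occ <- as_occupancy(occupancy)
  p <- field$params
  field$grid <- cpp_oxygen_advance(field$grid, occ, p$D_o, p$alpha_o,
                                   p$gamma_o, p$o_max, field$h_um * 1e-4,
                                   duration_h * 3600,
                                   identical(boundary, "reflect_rows"))
  field
}

#' Relax the oxygen field to its quasi-steady state
#'
#' Solves `D_o lap(o) = (alpha_o + gamma_o c) o` with Dirichlet boundaries by
#' successive over-relaxation, warm-started from the current field. Because
#' the field relaxes over the tumour in a few hundred seconds -- far faster
#' than the cellular update interval -- this is the engine's default
#' per-macro-step oxygen update.
#'
#' @inheritParams oxygen_advance
#' @param tol convergence tolerance on the maximum per-sweep update.
#' @param max_iter sweep cap.
#' @return the relaxed `oxygen_field` (with an `iterations` attribute).
#' @export
oxygen_steady <- function(field, occupancy, tol = 1e-8 * field$params$o_max,
                          max_iter = 100000) {
  occ <- as_occupancy(occupancy)
  p <- field$params
  res <- cpp_oxygen_steady(field$grid, occ, p$D_o, p$alpha_o, p$gamma_o,
                           p$o_max, field$h_um * 1e-4, tol, max_iter)
  field$grid <- res$field
  attr(field, "iterations") <- res$iterations
  field
}

#' Sites below the hypoxic death threshold
#'
#' @param field an `oxygen_field`.
#' @return tibble of 1-based lattice coordinates `(i, j)` where the
#'   concentration is strictly below `o_deadly`.
#' @export
hypoxic_sites <- function(field) {
  w <- which(field$grid < field$params$o_deadly, arr.ind = TRUE)
  tibble(i = as.integer(w[, 1]), j = as.integer(w[, 2]))
}

as_occupancy <- function(x) {
  if (inherits(x, "tumour_state")) return(x$occ)
  if (!is.matrix(x)) abort("`occupancy` must be a matrix or tumour_state")
  storage.mode(x) <- "integer"
  x
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf("<oxygen_field> %d x %d, range [%.4g, %.4g] (o_deadly = %g)\n",
              nrow(x$grid), ncol(x$grid), min(x$grid), max(x$grid),
              x$params$o_deadly))
  invisible(x)
}
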