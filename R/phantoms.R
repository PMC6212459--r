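# Synthetic phantom spheroids with known ground-truth morphometrics, so the
# metrics layer can be validated independently of the simulator. Each phantom
# is a regular tumour_state carrying a `ground_truth` attribute.

#' Disc phantom
#'
#' A completely filled lattice disc, identical in geometry to the simulator's
#' initial condition: all sites whose centres lie within `radius_um` of the
#' centre site are occupied.
#'
#' @param radius_um disc radius (um).
#' @param h_um site size (um).
#' @param n lattice side in sites (default sized generously around the disc).
#' @param phenotype adhesion preference assigned to every cell.
#' @return a `tumour_state` with attribute `ground_truth`:
#'   `invasive_radius_um` and `core_radius_um` (the exact maximum occupied
#'   site-centre distance) and `n_cells`.
#' @export
phantom_disc <- function(radius_um, h_um = 20, n = NULL, phenotype = 7L) {
  stopifnot(radius_um >= 0)
  r_sites <- radius_um / h_um
  if (is.null(n)) n <- 2L * (ceiling(r_sites) + 6L)
  if (r_sites >= n / 2) abort("disc does not fit in the lattice")
  geom <- lattice_geometry(L_mm = n * h_um / 1000, h_um = h_um)
  stopifnot(geom$n == n)
  c0 <- centre_site(n)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  d2 <- (ij$i - c0)^2 + (ij$j - c0)^2
  keep <- d2 <= r_sites^2 + 1e-9
  st <- place_cells(empty_state(geom), ij$i[keep], ij$j[keep], phenotype)
  truth <- list(invasive_radius_um = sqrt(max(d2[keep])) * h_um,
                core_radius_um = sqrt(max(d2[keep])) * h_um,
                n_cells = sum(keep))
  attr(st, "ground_truth") <- truth
  st
}

#' Starburst phantom (U87MG-like)
#'
#' A filled disc core plus detached single cells scattered at known radial
#' distances -- the non-cohesive invasion pattern. Singletons are placed so
#' that none touches the core or another singleton (each is its own
#' 8-connected component).
#'
#' @param core_radius_um core disc radius (um).
#' @param n_singletons number of detached cells.
#' @param max_range_um maximum singleton distance from the centre (um).
#' @param h_um site size (um).
#' @param core_phenotype,singleton_phenotype adhesion preferences.
#' @return a `tumour_state`; `ground_truth` holds the exact invasive radius
#'   (farthest singleton), core radius and cell count.
#' @export
phantom_starburst <- function(core_radius_um, n_singletons, max_range_um,
                              h_um = 20, core_phenotype = 7L,
                              singleton_phenotype = 0L) {
  stopifnot(max_range_um > core_radius_um + 3 * h_um || n_singletons == 0)
  n <- 2L * (ceiling(max_range_um / h_um) + 6L)
  st <- phantom_disc(core_radius_um, h_um, n, core_phenotype)
  truth <- attr(st, "ground_truth")
  c0 <- centre_site(n)
  placed <- 0L
  guard <- 0L
  max_d <- truth$invasive_radius_um
  while (placed < n_singletons) {
    guard <- guard + 1L
    if (guard > 10000L) abort("could not place singletons; enlarge the range")
    rad <- runif(1, core_radius_um + 3 * h_um, max_range_um)
    th <- runif(1, 0, 2 * pi)
    i <- round(c0 + rad / h_um * cos(th))
    j <- round(c0 + rad / h_um * sin(th))
    if (i < 2 || j < 2 || i > n - 1 || j > n - 1) next
    if (st$occ[i, j] != 0) next
    if (cpp_count_occupied_neighbours(st$occ, i - 1L, j - 1L, -1L, -1L) > 0) next
    st <- place_cells(st, i, j, singleton_phenotype)
    placed <- placed + 1L
    max_d <- max(max_d, sqrt((i - c0)^2 + (j - c0)^2) * h_um)
  }
  truth$invasive_radius_um <- max_d
  truth$n_cells <- truth$n_cells + placed
  truth$n_singletons <- placed
  attr(st, "ground_truth") <- truth
  st
}

#' Sprouted phantom (primary-like)
#'
#' A filled disc with finger-like cohesive protrusions: each sprout is a
#' Bresenham ray of cells from the core edge outward, so the whole phantom
#' remains one 8-connected component -- the sheet-like collective invasion
#' pattern with boundary instabilities.
#'
#' @param core_radius_um core disc radius (um).
#' @param n_sprouts number of protrusions (angles equally spaced, with a
#'   random common rotation).
#' @param sprout_length_um radial length of each protrusion (um).
#' @param h_um site size (um).
#' @param phenotype adhesion preference of all cells.
#' @return a `tumour_state`; `ground_truth` holds the exact invasive radius,
#'   the core radius of the underlying disc and the sprout length.
#' @export
phantom_sprouted <- function(core_radius_um, n_sprouts, sprout_length_um,
                             h_um = 20, phenotype = 5L) {
  reach <- core_radius_um + sprout_length_um
  n <- 2L * (ceiling(reach / h_um) + 6L)
  st <- phantom_disc(core_radius_um, h_um, n, phenotype)
  truth <- attr(st, "ground_truth")
  c0 <- centre_site(n)
  max_d <- truth$invasive_radius_um
  if (n_sprouts > 0) {
    rot <- runif(1, 0, 2 * pi)
    for (s in seq_len(n_sprouts)) {
      th <- rot + 2 * pi * (s - 1) / n_sprouts
      from <- c(c0 + core_radius_um / h_um * cos(th),
                c0 + core_radius_um / h_um * sin(th))
      to <- c(c0 + reach / h_um * cos(th), c0 + reach / h_um * sin(th))
      ray <- bresenham(round(from[1]), round(from[2]),
                       round(to[1]), round(to[2]))
      for (k in seq_len(nrow(ray))) {
        i <- ray[k, 1]; j <- ray[k, 2]
        if (i < 1 || j < 1 || i > n || j > n) next
        if (st$occ[i, j] == 0) st <- place_cells(st, i, j, phenotype)
        max_d <- max(max_d, sqrt((i - c0)^2 + (j - c0)^2) * h_um)
      }
    }
  }
  truth$invasive_radius_um <- max_d
  truth$sprout_length_um <- sprout_length_um
  truth$n_cells <- sum(st$cells$alive)
  attr(st, "ground_truth") <- truth
  st
}

# Integer line rasterisation; consecutive points are 8-adjacent.
bresenham <- function(i0, j0, i1, j1) {
  di <- abs(i1 - i0); dj <- abs(j1 - j0)
  si <- sign(i1 - i0); sj <- sign(j1 - j0)
  err <- di - dj
  out <- matrix(NA_integer_, di + dj + 1L, 2)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(i0, j0)
    if (i0 == i1 && j0 == j1) break
    e2 <- 2L * err
    if (e2 > -dj) { err <- err - dj; i0 <- i0 + si }
    if (e2 < di) { err <- err + di; j0 <- j0 + sj }
  }
  out[seq_len(k), , drop = FALSE]
}
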