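# Plain-text IO for snapshots and metric tables, shared by the engine and the
# command-line interface.

#' Write and read grid snapshots
#'
#' A snapshot is a CSV matrix of integer phenotype values per site, with -1
#' marking empty sites -- one row per lattice row, no header.
#'
#' @param state a `tumour_state`.
#' @param path file path.
#' @param h_um site size to assume when reading.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a `tumour_state` (ages and ids are not stored in snapshots and
#'   are reset).
#' @export
write_snapshot <- function(state, path) {
  m <- matrix(-1L, state$geometry$n, state$geometry$n)
  lc <- live_cells(state)
  m[cbind(lc$i, lc$j)] <- lc$phenotype
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path, h_um = 20) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) abort("snapshot must be square")
  geom <- lattice_geometry(L_mm = nrow(m) * h_um / 1000, h_um = h_um)
  w <- which(m >= 0, arr.ind = TRUE)
  place_cells(empty_state(geom), w[, 1], w[, 2], m[w])
}

#' Write a metric time-series table
#'
#' @param metrics metrics tibble of a run or the `runs` table of an ensemble.
#' @param path file path.
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write and read oxygen-grid snapshots
#'
#' Plain CSV matrix of concentrations, one row per lattice row, no header.
#'
#' @param field an `oxygen_field`.
#' @param path file path.
#' @param params an [oxygen_params()] to attach when reading.
#' @param h_um site size to assume when reading.
#' @export
write_oxygen_snapshot <- function(field, path) {
  utils::write.table(field$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_oxygen_snapshot
#' @export
read_oxygen_snapshot <- function(path, params = oxygen_params(), h_um = 20) {
  g <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(g) <- NULL
  f <- oxygen_field(NULL, params, dim = dim(g))
  f$grid <- g
  f$h_um <- h_um
  f
}
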