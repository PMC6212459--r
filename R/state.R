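# Tumour state: occupancy grid + cell registry + event log, kept mutually
# consistent. Cell ids are allocated monotonically and never reused, so the
# registry row k always holds cell id k and the event log is unambiguous.

new_tumour_state <- function(geometry, occ, cells, time_h = 0,
                             events = empty_events()) {
  structure(list(geometry = geometry, occ = occ, cells = cells,
                 time_h = time_h, events = events,
                 centre = centre_site(geometry$n)),
            class = "tumour_state")
}

empty_events <- function() {
  tibble(time_h = numeric(), event = character(),
         cell = integer(), detail = integer())
}

event_names <- c("division", "death", "switch", "move")

decode_events <- function(df) {
  tibble(time_h = df$time_h, event = event_names[df$event],
         cell = df$cell, detail = df$detail)
}

#' Construct an empty tumour state
#'
#' @param geometry a [lattice_geometry()].
#' @return a `tumour_state` with no cells at time 0.
#' @export
empty_state <- function(geometry = lattice_geometry()) {
  n <- geometry$n
  occ <- matrix(0L, n, n)
  cells <- tibble(id = integer(), i = integer(), j = integer(),
                  phenotype = integer(), age = numeric(),
                  quiescent = logical(), alive = logical())
  new_tumour_state(geometry, occ, cells, 0)
}

#' Place cells on a state
#'
#' Adds live cells at the given (row, column) lattice sites (1-based). Used by
#' the phantom generators and tests; the simulator initialises via
#' [sim_init()].
#'
#' @param state a `tumour_state`.
#' @param i,j 1-based lattice coordinates of the new cells.
#' @param phenotype adhesion preference(s), recycled along `i`.
#' @param age initial age(s) in hours, recycled.
#' @return the updated `tumour_state`.
#' @export
place_cells <- function(state, i, j, phenotype = 7L, age = 0) {
  stopifnot(length(i) == length(j))
  n <- state$geometry$n
  if (any(i < 1 | i > n | j < 1 | j > n)) abort("cell positions outside lattice")
  if (any(state$occ[cbind(i, j)] != 0)) abort("site already occupied")
  if (anyDuplicated(cbind(i, j))) abort("duplicate cell positions")
  k <- length(i)
  phenotype <- validate_phenotype(rep_len(phenotype, k))
  age <- rep_len(age, k)
  last <- if (nrow(state$cells)) max(state$cells$id) else 0L
  ids <- last + seq_len(k)
  state$occ[cbind(i, j)] <- ids
  state$cells <- bind_rows(state$cells, tibble(
    id = as.integer(ids), i = as.integer(i), j = as.integer(j),
    phenotype = phenotype, age = as.numeric(age),
    quiescent = FALSE, alive = TRUE))
  state
}

#' Live cells of a state
#'
#' @param state a `tumour_state`.
#' @return tibble of live cells with physical positions (`x_um`, `y_um`
#'   measured from the initial-disc centre site) appended.
#' @export
live_cells <- function(state) {
  h <- state$geometry$h_um
  c0 <- state$centre
  state$cells |>
    filter(.data$alive) |>
    mutate(x_um = (.data$i - c0) * h, y_um = (.data$j - c0) * h,
           dist_um = sqrt(.data$x_um^2 + .data$y_um^2))
}

#' Audit occupancy/registry consistency
#'
#' Diagnostic check of the exclusion-process bookkeeping: every live cell must
#' sit on exactly one occupied site referring back to it, every occupied site
#' must refer to a live cell, and dead cells must occupy nothing.
#'
#' @param state a `tumour_state`.
#' @return `TRUE` if the occupancy grid and cell registry form a bijection,
#'   otherwise `FALSE`.
#' @export
audit_consistency <- function(state) {
  occ <- state$occ
  cells <- state$cells
  live <- cells[cells$alive, ]
  occ_ids <- occ[occ != 0L]
  if (anyDuplicated(occ_ids)) return(FALSE)
  if (length(occ_ids) != nrow(live)) return(FALSE)
  if (!setequal(occ_ids, live$id)) return(FALSE)
  all(occ[cbind(live$i, live$j)] == live$id)
}

#' @export
print.tumour_state <- function(x, ...) {
  nlive <- sum(x$cells$alive)
  cat(sprintf("<tumour_state> %d x %d lattice (h = %g um), t = %g h, %d live cells\n",
              x$geometry$n, x$geometry$n, x$geometry$h_um, x$time_h, nlive))
  invisible(x)
}

# ---- packing to/from the C++ engine representation (0-based coords) ----

pack_state <- function(state) {
  cells <- state$cells
  list(occ = state$occ,
       cells = list(i = cells$i - 1L, j = cells$j - 1L,
                    phenotype = cells$phenotype, age = cells$age,
                    quiescent = cells$quiescent, alive = cells$alive))
}

unpack_cells_df <- function(cells) {
  tibble(id = seq_along(cells$i), i = cells$i + 1L, j = cells$j + 1L,
         phenotype = as.integer(cells$phenotype), age = as.numeric(cells$age),
         quiescent = as.logical(cells$quiescent),
         alive = as.logical(cells$alive))
}
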