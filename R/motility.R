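# Adhesion-gated, diffusion-derived random movement. The cell diffusion
# equation dc/dt = D_c lap(c) is discretised to per-cell movement
# probabilities: in a substep of k seconds a cell attempts a move with
# probability p_move = 4 D_c k / h^2 (5-point-stencil derivation), and the
# attempt succeeds only onto an empty Moore neighbour whose occupied-neighbour
# count (excluding the mover) equals the cell's adhesion preference.

#' Build a movement kernel
#'
#' Chooses the substep so the move probability stays a probability: if
#' `D_c > 0`, `k = min(t_r, h^2 / (4 D_c))` seconds, rounded so an integer
#' number of substeps tiles `t_r` exactly, giving `p_move = 4 D_c k / h^2 <= 1`.
#'
#' @param D_c cell diffusion coefficient (cm^2/s).
#' @param h_um lattice site size (um).
#' @param t_r_h update interval (hours).
#' @return a `move_kernel` list with `D_c`, `k_s` (substep, seconds),
#'   `n_substeps` and `p_move`.
#' @examples
#' move_kernel(5e-9)  # 15 substeps of 192 s, p_move 0.96
#' @export
move_kernel <- function(D_c, h_um = 20, t_r_h = 0.8) {
  if (D_c < 0 || h_um <= 0 || t_r_h <= 0) {
    abort("`D_c` must be >= 0 and `h_um`, `t_r_h` positive")
  }
  if (D_c == 0) {
    k <- structure(list(D_c = 0, k_s = t_r_h * 3600, n_substeps = 1L,
                        p_move = 0), class = "move_kernel")
    return(k)
  }
  h_cm <- h_um * 1e-4
  t_r_s <- t_r_h * 3600
  k_s <- min(t_r_s, h_cm^2 / (4 * D_c))
  n <- ceiling(t_r_s / k_s - 1e-12)
  k_s <- t_r_s / n
  structure(list(D_c = D_c, k_s = k_s, n_substeps = as.integer(n),
                 p_move = 4 * D_c * k_s / h_cm^2),
            class = "move_kernel")
}

#' Occupied Moore neighbours of a site
#'
#' Counts live-cell-occupied sites among the 8 Moore neighbours of `(i, j)`,
#' optionally excluding one cell (the prospective mover) wherever it sits.
#' Sites beyond the lattice border count as empty.
#'
#' @param state a `tumour_state`.
#' @param i,j 1-based site coordinates.
#' @param exclude optional cell id to ignore.
#' @return integer in `0:8`.
#' @export
occupied_neighbours <- function(state, i, j, exclude = NULL) {
  n <- state$geometry$n
  if (i < 1 || i > n || j < 1 || j > n) abort("site outside lattice")
  ei <- ej <- -1L
  if (!is.null(exclude)) {
    row <- state$cells[state$cells$id == exclude, ]
    if (nrow(row) == 1 && row$alive) { ei <- row$i - 1L; ej <- row$j - 1L }
  }
  cpp_count_occupied_neighbours(state$occ, i - 1L, j - 1L, ei, ej)
}

#' Admissible movement destinations of a cell
#'
#' The empty Moore-adjacent sites whose occupied-neighbour count (excluding
#' the cell itself) equals the cell's adhesion preference. May be empty; a
#' cell with no admissible destination forfeits its movement attempt.
#'
#' @param state a `tumour_state`.
#' @param cell a live cell id.
#' @return tibble of 1-based destinations `(i, j)`.
#' @export
admissible_destinations <- function(state, cell) {
  row <- state$cells[state$cells$id == cell, ]
  if (nrow(row) != 1 || !row$alive) abort("`cell` must be a live cell id")
  m <- cpp_admissible_destinations(state$occ, row$i - 1L, row$j - 1L,
                                   row$phenotype)
  tibble(i = m[, 1] + 1L, j = m[, 2] + 1L)
}

#' One cell's movement turn
#'
#' Runs the kernel's substeps for a single cell: each substep, with
#' probability `p_move` the cell relocates to an admissible destination chosen
#' uniformly at random (occupancy and registry updated atomically), otherwise
#' it stays put.
#'
#' @param state a `tumour_state`.
#' @param cell a live cell id.
#' @param kernel a [move_kernel()].
#' @param move_rule `"proposal"` (per-direction proposal with veto; the
#'   engine default) or `"renormalised"` (uniform choice among admissible
#'   destinations); see [sim_config()].
#' @return the updated `tumour_state` (moves appended to the event log when
#'   the state was built from a config with `log_moves = TRUE`; here they are
#'   always logged).
#' @export
attempt_move <- function(state, cell, kernel,
                         move_rule = c("proposal", "renormalised")) {
  move_rule <- arg_match(move_rule)
  row <- state$cells[state$cells$id == cell, ]
  if (nrow(row) != 1 || !row$alive) abort("`cell` must be a live cell id")
  p <- pack_state(state)
  res <- cpp_move_turn(p$occ, p$cells, cell, kernel$p_move,
                       kernel$n_substeps,
                       identical(move_rule, "renormalised"), TRUE,
                       state$time_h)
  state$occ <- res$occ
  state$cells <- unpack_cells_df(res$cells)
  if (nrow(res$events)) {
    state$events <- bind_rows(state$events, decode_events(res$events))
  }
  state
}
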