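# Cell life cycle: age-based proliferation with space search and quiescence,
# mitotic phenotype switching, and hypoxic death.

#' One cell's lifecycle turn
#'
#' Below its division age the cell simply ages by `t_r`. At or past it (or
#' while quiescent) the cell searches the Moore neighbourhood of radius
#' `prolif_radius` for empty sites: with none it enters (or stays in)
#' quiescence with its age frozen; otherwise a daughter is placed uniformly at
#' random on one of the empty sites, both cells' ages reset to 0, quiescence
#' clears, and the mitotic phenotype switch is applied -- with probability
#' `p_mut` a phenotype drawn uniformly from the allowed set replaces the
#' parent phenotype in BOTH daughters. A quiescent cell next to newly vacated
#' space therefore divides on its next lifecycle turn.
#'
#' @param state a `tumour_state`.
#' @param cell a live cell id.
#' @param config the `sim_config` supplying `T_p_h`, `prolif_radius`,
#'   `p_mut`, the allowed phenotype set and `t_r_h`.
#' @return the updated `tumour_state` with division/switch events logged.
#' @export
attempt_division <- function(state, cell, config) {
  row <- state$cells[state$cells$id == cell, ]
  if (nrow(row) != 1 || !row$alive) abort("`cell` must be a live cell id")
  p <- pack_state(state)
  res <- cpp_division_turn(p$occ, p$cells, cell, expand_T_p(config),
                           as.integer(config$prolif_radius), config$t_r_h,
                           config$p_mut, as.integer(config$phenotypes))
  state$occ <- res$occ
  state$cells <- unpack_cells_df(res$cells)
  if (res$divided) {
    ev <- tibble(time_h = state$time_h, event = "division",
                 cell = res$daughter, detail = cell)
    if (res$switched) {
      ev <- bind_rows(ev, tibble(time_h = state$time_h, event = "switch",
                                 cell = cell, detail = res$new_ph))
    }
    state$events <- bind_rows(state$events, ev)
  }
  state
}

#' Mitotic phenotype switch
#'
#' With probability `p_mut`, returns a phenotype drawn uniformly from
#' `target_set` (self-transitions allowed -- all transitions are equally
#' likely); otherwise returns the parent phenotype unchanged. At a division
#' the sampled phenotype is applied to both daughter cells.
#'
#' @param parent parent adhesion preference (0--7).
#' @param p_mut switch probability in `[0, 1]`.
#' @param target_set non-empty integer set of allowed phenotypes.
#' @return the (possibly switched) phenotype.
#' @export
apply_phenotype_switch <- function(parent, p_mut, target_set) {
  parent <- validate_phenotype(parent, "parent")
  if (length(target_set) == 0) abort("`target_set` must be non-empty")
  target_set <- validate_phenotype(target_set, "target_set")
  stopifnot(p_mut >= 0, p_mut <= 1)
  if (runif(1) < p_mut) {
    target_set[[floor(runif(1) * length(target_set)) + 1]]
  } else {
    parent
  }
}

#' Hypoxic death sweep
#'
#' Marks every live cell sitting on a hypoxic site (oxygen strictly below
#' `o_deadly`) as dead, frees its lattice site (dead cells are treated as
#' empty space) and logs the deaths.
#'
#' @param state a `tumour_state`.
#' @param field an `oxygen_field` synchronised with the state.
#' @return the updated `tumour_state`.
#' @export
apply_hypoxic_death <- function(state, field) {
  if (!all(dim(field$grid) == dim(state$occ))) {
    abort("oxygen field and state have mismatched dimensions")
  }
  p <- pack_state(state)
  res <- cpp_death_pass(p$occ, p$cells, field$grid,
                        field$params$o_deadly, state$time_h)
  state$occ <- res$occ
  state$cells <- unpack_cells_df(res$cells)
  if (nrow(res$events)) {
    state$events <- bind_rows(state$events, decode_events(res$events))
  }
  state
}
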