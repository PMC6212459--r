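# The asynchronous scheduler: initialisation, macro-steps, full runs and
# replicate ensembles. Every macro-step of t_r hours executes, in order, a
# movement pass (fresh random permutation of live cells), the oxygen update
# over t_r, and a lifecycle pass (fresh permutation; divisions, then a
# hypoxic-death sweep against the freshly updated field).

#' Initialise a spheroid simulation
#'
#' Fills a disc of the configured radius at the domain centre completely with
#' cells: phenotypes drawn i.i.d. from the initial mixture, ages uniform on
#' `[0, T_p)` (avoiding synchronised division waves), oxygen uniform at
#' `o_max`, clock at 0.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (`set.seed()` is called when given).
#' @return a `sim_world`: list with elements `state` (a `tumour_state`) and
#'   `oxygen` (an `oxygen_field`).
#' @export
sim_init <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geom <- config$geometry
  n <- geom$n
  c0 <- centre_site(n)
  r_sites <- config$initial_radius_um / geom$h_um
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  keep <- (ij$i - c0)^2 + (ij$j - c0)^2 <= r_sites^2 + 1e-9
  ij <- ij[keep, ]
  k <- nrow(ij)
  ph <- config$phenotypes[sample.int(length(config$phenotypes), k,
                                     replace = TRUE, prob = config$mixture)]
  Tp8 <- expand_T_p(config)
  age <- runif(k) * Tp8[ph + 1]
  state <- place_cells(empty_state(geom), ij$i, ij$j, ph, age)
  oxy <- oxygen_field(geom, config$oxygen)
  structure(list(state = state, oxygen = oxy), class = "sim_world")
}

#' Advance a simulation by one macro-step
#'
#' @param world a `sim_world` from [sim_init()].
#' @param config the `sim_config` used to create it.
#' @return the advanced `sim_world`.
#' @export
sim_step <- function(world, config) {
  cfg <- engine_cfg(config)
  cfg$t_max_h <- world$state$time_h + config$t_r_h
  cfg$record_every_h <- 2 * config$t_r_h  # no intermediate recording
  p <- pack_state(world$state)
  res <- cpp_run(p$occ, p$cells, world$oxygen$grid, world$state$time_h, cfg)
  world$state$occ <- res$occ
  world$state$cells <- unpack_cells_df(res$cells)
  world$state$time_h <- round(res$time_h, 6)
  if (nrow(res$events)) {
    world$state$events <- bind_rows(world$state$events,
                                    decode_events(res$events))
  }
  world$oxygen$grid <- res$field
  world
}

#' Run a spheroid simulation
#'
#' Steps the world until the time horizon `t_max_h` is reached or any cell
#' comes within `edge_margin` sites of the lattice border, recording the
#' morphometric series every `record_every_h` hours (and at the final state).
#' A (config, seed) pair fully determines every output.
#'
#' @param config a [sim_config()].
#' @param seed integer replicate seed.
#' @param stop_at_first_death additionally stop as soon as the first hypoxic
#'   death occurs (used when only the necrosis onset time is of interest).
#' @return a `spheroid_sim` object: `metrics` (tibble time series), `state`,
#'   `oxygen`, `events`, `config`, `seed`, `stop_reason`, `first_death_h`.
#' @examples
#' cfg <- config_u87mg(t_max_h = 8)
#' run <- sim_run(cfg, seed = 1)
#' run$metrics
#' @export
sim_run <- function(config, seed = 1L, stop_at_first_death = FALSE) {
  world <- sim_init(config, seed = seed)
  cfg <- engine_cfg(config)
  cfg$stop_at_first_death <- isTRUE(stop_at_first_death)
  p <- pack_state(world$state)
  res <- cpp_run(p$occ, p$cells, world$oxygen$grid, 0, cfg)

  metrics <- as_tibble(res$metrics)
  metrics$time_h <- round(metrics$time_h, 6)
  freq <- res$freq
  colnames(freq) <- paste0("freq_", 0:7)
  metrics <- bind_cols(metrics, as_tibble(freq))
  if (identical(config$cell_line, "primary")) {
    # the primary morphology has no separable maternal core
    metrics$core_radius_um <- NA_real_
  }
  metrics <- mutate(metrics,
                    invasive_rim_um = .data$invasive_radius_um - .data$core_radius_um,
                    .after = "core_radius_um")

  world$state$occ <- res$occ
  world$state$cells <- unpack_cells_df(res$cells)
  world$state$time_h <- round(res$time_h, 6)
  world$state$events <- decode_events(res$events)
  world$oxygen$grid <- res$field

  structure(list(metrics = metrics, state = world$state,
                 oxygen = world$oxygen, events = world$state$events,
                 config = config, seed = seed,
                 stop_reason = res$stop_reason,
                 first_death_h = res$first_death_h),
            class = "spheroid_sim")
}

#' Run a replicate ensemble
#'
#' `n` independent runs with seeds `seed + 0:(n-1)`; variation between
#' replicates comes from the random initial phenotypes and ages and from the
#' stochastic movement, division and switching.
#'
#' @inheritParams sim_run
#' @param n number of replicates.
#' @param keep_states retain each replicate's final `tumour_state` (off by
#'   default to bound memory).
#' @return a `spheroid_ensemble`: per-replicate metric series (`runs`), a
#'   per-timepoint `summary` tibble of ensemble means and standard deviations,
#'   the seeds, per-replicate stop reasons and first-death times.
#' @export
sim_replicates <- function(config, n = 50, seed = 1L,
                           stop_at_first_death = FALSE, keep_states = FALSE) {
  stopifnot(n >= 1)
  seeds <- seed + seq_len(n) - 1L
  runs <- vector("list", n)
  states <- if (keep_states) vector("list", n) else NULL
  stop_reason <- character(n)
  first_death_h <- numeric(n)
  for (r in seq_len(n)) {
    s <- sim_run(config, seed = seeds[r],
                 stop_at_first_death = stop_at_first_death)
    runs[[r]] <- mutate(s$metrics, replicate = r, .before = 1)
    stop_reason[r] <- s$stop_reason
    first_death_h[r] <- s$first_death_h
    if (keep_states) states[[r]] <- s$state
  }
  all_metrics <- bind_rows(runs)
  metric_cols <- setdiff(names(all_metrics), c("replicate", "time_h"))
  summary <- all_metrics |>
    group_by(.data$time_h) |>
    summarise(n_runs = dplyr::n(),
              across(all_of(metric_cols),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))),
              .groups = "drop")
  structure(list(runs = all_metrics, summary = summary, config = config,
                 seeds = seeds, stop_reason = stop_reason,
                 first_death_h = first_death_h, states = states),
            class = "spheroid_ensemble")
}

#' @export
print.spheroid_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(paste0("<spheroid_sim> %s, seed %d: stopped at %g h (%s), ",
                     "%d cells, invasive radius %.0f um\n"),
              x$config$cell_line, x$seed, x$state$time_h, x$stop_reason,
              as.integer(last$n_cells), last$invasive_radius_um))
  invisible(x)
}

#' @export
print.spheroid_ensemble <- function(x, ...) {
  cat(sprintf("<spheroid_ensemble> %s, %d replicates (seeds %d..%d)\n",
              x$config$cell_line, length(x$seeds), min(x$seeds), max(x$seeds)))
  invisible(x)
}
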