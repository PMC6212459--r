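# Simulation configuration: lattice geometry, kinetic parameters, phenotype
# mixtures, oxygen parameters, motility phases, scenario presets and YAML IO.

# Per-cell oxygen consumption rate (1/s) calibrated so that, in the primary
# scenario, the ensemble-median time of the first hypoxia-induced death falls
# near 150 h (see the methods vignette for the calibration procedure).
.gamma_o_calibrated <- 0.012

#' Lattice geometry
#'
#' The computational domain is a square 2D exclusion lattice: a planar slice
#' through a 3D spheroid in which each `h x h` site holds at most one cell.
#'
#' @param L_mm physical side length of the domain in mm.
#' @param h_um lattice site size in micrometres (one cell diameter).
#' @return a `lattice_geometry` list with fields `L_mm`, `h_um` and `n`
#'   (sites per side, `round(L / h)`).
#' @examples
#' lattice_geometry()  # 5 mm at 20 um -> 250 x 250 sites
#' @export
lattice_geometry <- function(L_mm = 5, h_um = 20) {
  stopifnot(L_mm > 0, h_um > 0)
  n <- as.integer(round(L_mm * 1000 / h_um))
  if (n < 3) abort("lattice must be at least 3 sites per side")
  structure(list(L_mm = L_mm, h_um = h_um, n = n), class = "lattice_geometry")
}

#' Motility phases
#'
#' Tumour expansion can be governed by different motility rates in different
#' time windows (e.g. a fast early dispersal phase followed by slower
#' spreading). Each phase is a diffusion coefficient `D_c` applying up to its
#' end time; the last phase extends to the end of the simulation.
#'
#' @param D_c numeric vector of cell diffusion coefficients (cm^2/s), one per
#'   phase.
#' @param t_end_h end time (hours) of each phase; the last entry may be `Inf`.
#' @return a tibble with columns `t_end_h`, `D_c` of class `motility_phases`.
#' @examples
#' motility_phases(c(1.5e-8, 3e-9), c(24, Inf))
#' @export
motility_phases <- function(D_c, t_end_h = Inf) {
  stopifnot(length(D_c) == length(t_end_h), all(D_c >= 0))
  if (is.unsorted(t_end_h, strictly = TRUE)) {
    abort("`t_end_h` must be strictly increasing")
  }
  out <- tibble(t_end_h = as.numeric(t_end_h), D_c = as.numeric(D_c))
  class(out) <- c("motility_phases", class(out))
  out
}

#' Oxygen parameters
#'
#' Parameters of the oxygen reaction-diffusion field: oxygen diffuses from the
#' domain boundary (held at `o_max`, mimicking the culture medium), decays
#' naturally at rate `alpha_o`, and is consumed by live tumour cells at rate
#' `gamma_o`. Cells on sites where the concentration falls below `o_deadly`
#' die. Concentrations are normalised so `o_max = 1`.
#'
#' The default `gamma_o` is calibrated so that necrosis first appears near
#' 150 h in the primary-cell scenario (see the methods vignette).
#'
#' @param D_o oxygen diffusion coefficient (cm^2/s).
#' @param alpha_o natural decay rate (1/s).
#' @param gamma_o per-cell consumption rate (1/s).
#' @param o_max boundary/initial concentration (normalised).
#' @param o_deadly hypoxic death threshold (same units as `o_max`).
#' @return an `oxygen_params` list.
#' @export
oxygen_params <- function(D_o = 1e-5, alpha_o = 0,
                          gamma_o = .gamma_o_calibrated,
                          o_max = 1, o_deadly = 0.1) {
  stopifnot(D_o > 0, alpha_o >= 0, gamma_o >= 0, o_max > 0,
            o_deadly >= 0, o_deadly < o_max)
  structure(list(D_o = D_o, alpha_o = alpha_o, gamma_o = gamma_o,
                 o_max = o_max, o_deadly = o_deadly),
            class = "oxygen_params")
}

#' Simulation configuration
#'
#' Full parameterisation of one in silico spheroid scenario.
#'
#' @param geometry a [lattice_geometry()].
#' @param phenotypes integer vector of allowed adhesion preferences (0--7).
#' @param mixture initial mixture probabilities over `phenotypes`; defaults to
#'   uniform. Must sum to 1.
#' @param initial_radius_um radius (um) of the initial fully-filled disc of
#'   cells at the domain centre.
#' @param T_p_h proliferation (division) age in hours; either a single value
#'   shared by all phenotypes or a named vector keyed by adhesion preference
#'   (e.g. `c("2" = 50, "6" = 25)`) with unnamed default taken from `default_T_p_h`.
#' @param phases a [motility_phases()] object (or a single `D_c` value).
#' @param p_mut probability that a division stochastically switches the
#'   phenotype; the new phenotype is drawn uniformly from `phenotypes` and
#'   applied to both daughters.
#' @param oxygen an [oxygen_params()] object.
#' @param t_r_h asynchronous update interval (hours) between macro-steps.
#' @param t_max_h simulation horizon in hours (default 9 days).
#' @param edge_margin stop the run once any cell comes within this many sites
#'   of the lattice border.
#' @param prolif_radius Moore-neighbourhood radius (sites) searched for empty
#'   space at division.
#' @param record_every_h interval (hours) between morphometric recordings.
#' @param cell_line one of `"u87mg"`, `"primary"`, `"custom"`; controls
#'   whether a connectivity-based core radius is meaningful (it is reported as
#'   missing for the primary morphology, whose core cannot be separated from
#'   the invasive area).
#' @param oxygen_solver `"steady"` (quasi-steady-state relaxation each
#'   macro-step; the default), `"transient"` (explicit time integration) or
#'   `"frozen"` (field held fixed; no hypoxic death).
#' @param move_rule how a movement attempt uses the adhesion preference:
#'   `"proposal"` (default) proposes one of the 8 Moore directions uniformly
#'   at the diffusion-derived per-direction rate and vetoes proposals that are
#'   occupied or do not match the preference; `"renormalised"` relocates with
#'   the full attempt probability uniformly among whatever admissible
#'   destinations exist. Both give identical free-space kinetics; see the
#'   methods vignette for why the proposal rule is the default.
#' @param log_moves,log_lifecycle record individual move / division-death
#'   events in the event log. Moves are off by default to bound log size.
#' @return a `sim_config` list.
#' @seealso [config_u87mg()], [config_primary()] for the two cell-line presets.
#' @export
sim_config <- function(geometry = lattice_geometry(),
                       phenotypes = 0:7,
                       mixture = NULL,
                       initial_radius_um = 140,
                       T_p_h = 31,
                       phases = motility_phases(5e-9),
                       p_mut = 0,
                       oxygen = oxygen_params(),
                       t_r_h = 0.8,
                       t_max_h = 216,
                       edge_margin = 5,
                       prolif_radius = 2,
                       record_every_h = 8,
                       cell_line = c("custom", "u87mg", "primary"),
                       oxygen_solver = c("steady", "transient", "frozen"),
                       move_rule = c("proposal", "renormalised"),
                       log_moves = FALSE,
                       log_lifecycle = TRUE) {
  cell_line <- arg_match(cell_line)
  oxygen_solver <- arg_match(oxygen_solver)
  move_rule <- arg_match(move_rule)
  phenotypes <- validate_phenotype(phenotypes, "phenotypes")
  if (anyDuplicated(phenotypes)) abort("`phenotypes` must be distinct")
  if (is.null(mixture)) mixture <- rep(1 / length(phenotypes), length(phenotypes))
  if (length(mixture) != length(phenotypes) || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-8) {
    abort("`mixture` must be non-negative, match `phenotypes` in length and sum to 1")
  }
  if (is.numeric(phases)) phases <- motility_phases(phases)
  stopifnot(inherits(phases, "motility_phases"))
  stopifnot(t_r_h > 0, t_max_h >= 0, edge_margin >= 1, prolif_radius >= 1,
            record_every_h > 0, all(T_p_h > 0))
  if (initial_radius_um >= geometry$L_mm * 1000 / 2) {
    abort("`initial_radius_um` must be smaller than half the domain side")
  }
  structure(list(
    geometry = geometry, phenotypes = phenotypes, mixture = mixture,
    initial_radius_um = initial_radius_um,
    T_p_h = T_p_h, phases = phases, p_mut = p_mut, oxygen = oxygen,
    t_r_h = t_r_h, t_max_h = t_max_h, edge_margin = edge_margin,
    prolif_radius = prolif_radius, record_every_h = record_every_h,
    cell_line = cell_line, oxygen_solver = oxygen_solver,
    move_rule = move_rule,
    log_moves = log_moves, log_lifecycle = log_lifecycle
  ), class = "sim_config")
}

#' Scenario presets for the two cell lines
#'
#' `config_u87mg()` models the U87MG line: a mixture of low- and high-adhesive
#' phenotypes (0, 1, 6, 7), division age 31 h, initial disc radius 140 um.
#' Its two-phase motility uses `D_c = 1.5e-8 cm^2/s` during the first 24 h and
#' `3e-9` afterwards (single phase: `5e-9`).
#'
#' `config_primary()` models the patient-derived primary line: middle- and
#' high-adhesive phenotypes (2--7), division age 25 h, initial disc radius
#' 200 um. Its two-phase motility uses `D_c = 4e-10 cm^2/s` before 24 h and
#' `4e-8` afterwards (single phase: `2e-8`).
#'
#' @param two_phase use the two-phase motility rates (default) or the single
#'   constant rate.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @examples
#' cfg <- config_u87mg(t_max_h = 8)
#' cfg$phenotypes
#' @export
config_u87mg <- function(two_phase = TRUE, ...) {
  phases <- if (two_phase) {
    motility_phases(c(1.5e-8, 3e-9), c(24, Inf))
  } else {
    motility_phases(5e-9)
  }
  defaults <- list(phenotypes = c(0L, 1L, 6L, 7L), T_p_h = 31,
                   initial_radius_um = 140, phases = phases,
                   cell_line = "u87mg")
  do.call(sim_config, modifyList(defaults, list(...)))
}

#' @rdname config_u87mg
#' @export
config_primary <- function(two_phase = TRUE, ...) {
  phases <- if (two_phase) {
    motility_phases(c(4e-10, 4e-8), c(24, Inf))
  } else {
    motility_phases(2e-8)
  }
  defaults <- list(phenotypes = 2:7, T_p_h = 25,
                   initial_radius_um = 200, phases = phases,
                   cell_line = "primary")
  do.call(sim_config, modifyList(defaults, list(...)))
}

# Expand T_p_h into a length-8 vector indexed by adhesion value 0..7.
expand_T_p <- function(config) {
  Tp <- config$T_p_h
  out <- rep(NA_real_, 8)
  if (is.null(names(Tp))) {
    if (length(Tp) != 1) abort("unnamed `T_p_h` must be a single value")
    out[] <- Tp
  } else {
    default <- if (any(names(Tp) == "")) Tp[names(Tp) == ""][1] else NA_real_
    out[] <- default
    keyed <- Tp[names(Tp) != ""]
    out[as.integer(names(keyed)) + 1] <- keyed
  }
  if (anyNA(out[config$phenotypes + 1])) {
    abort("`T_p_h` does not cover every phenotype in the mixture")
  }
  out[is.na(out)] <- max(out, na.rm = TRUE)  # inert: phenotypes not in play
  out
}

# Flatten a config to the list the C++ engine expects.
engine_cfg <- function(config) {
  ph <- config$phases
  list(
    h_um = config$geometry$h_um,
    t_r_h = config$t_r_h,
    t_max_h = config$t_max_h,
    record_every_h = config$record_every_h,
    edge_margin = as.integer(config$edge_margin),
    T_p8_h = expand_T_p(config),
    prolif_radius = as.integer(config$prolif_radius),
    phase_end_h = ph$t_end_h,
    phase_D = ph$D_c,
    p_mut = config$p_mut,
    target_set = as.integer(config$phenotypes),
    D_o = config$oxygen$D_o, alpha_o = config$oxygen$alpha_o,
    gamma_o = config$oxygen$gamma_o, o_max = config$oxygen$o_max,
    o_deadly = config$oxygen$o_deadly,
    oxygen_solver_code = switch(config$oxygen_solver,
                                frozen = 0L, steady = 1L, transient = 2L),
    steady_tol = 1e-8 * config$oxygen$o_max,
    move_renormalised = identical(config$move_rule, "renormalised"),
    log_moves = isTRUE(config$log_moves),
    log_lifecycle = isTRUE(config$log_lifecycle),
    stop_at_first_death = FALSE,
    centre0 = centre_site(config$geometry$n) - 1
  )
}

# 1-based index of the site on which the initial disc is centred. For an even
# side length the exact domain centre falls between sites; the disc is
# anchored on site n/2 + 1 (0-based n/2) so integer lattice-disc enumeration
# is exact. Radii are measured from this site's centre.
centre_site <- function(n) as.integer(n %/% 2L + 1L)

#' Read and write simulation configurations as YAML
#'
#' Configurations serialise to a flat YAML mapping with documented units
#' (hours, micrometres, cm^2/s) so scenarios can be stored alongside outputs.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- list(
    L_mm = config$geometry$L_mm, h_um = config$geometry$h_um,
    phenotypes = as.integer(config$phenotypes), mixture = config$mixture,
    initial_radius_um = config$initial_radius_um,
    T_p_h = as.list(config$T_p_h),
    phase_end_h = config$phases$t_end_h, phase_D_cm2_s = config$phases$D_c,
    p_mut = config$p_mut,
    D_o_cm2_s = config$oxygen$D_o, alpha_o_per_s = config$oxygen$alpha_o,
    gamma_o_per_s = config$oxygen$gamma_o, o_max = config$oxygen$o_max,
    o_deadly = config$oxygen$o_deadly,
    t_r_h = config$t_r_h, t_max_h = config$t_max_h,
    edge_margin_sites = config$edge_margin,
    prolif_radius_sites = config$prolif_radius,
    record_every_h = config$record_every_h,
    cell_line = config$cell_line, oxygen_solver = config$oxygen_solver,
    move_rule = config$move_rule,
    log_moves = config$log_moves, log_lifecycle = config$log_lifecycle
  )
  # Inf is not portable YAML; encode as the string ".inf"
  x$phase_end_h <- ifelse(is.infinite(x$phase_end_h), ".inf", x$phase_end_h)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  ends <- vapply(x$phase_end_h, function(e) {
    if (identical(e, ".inf")) Inf else as.numeric(e)
  }, numeric(1))
  Tp <- unlist(x$T_p_h)
  sim_config(
    geometry = lattice_geometry(x$L_mm, x$h_um),
    phenotypes = as.integer(unlist(x$phenotypes)),
    # renormalise: YAML serialisation truncates floats
    mixture = {
      m <- as.numeric(unlist(x$mixture))
      m / sum(m)
    },
    initial_radius_um = x$initial_radius_um, T_p_h = Tp,
    phases = motility_phases(unlist(x$phase_D_cm2_s), ends),
    p_mut = x$p_mut,
    oxygen = oxygen_params(x$D_o_cm2_s, x$alpha_o_per_s, x$gamma_o_per_s,
                           x$o_max, x$o_deadly),
    t_r_h = x$t_r_h, t_max_h = x$t_max_h, edge_margin = x$edge_margin_sites,
    prolif_radius = x$prolif_radius_sites, record_every_h = x$record_every_h,
    cell_line = x$cell_line, oxygen_solver = x$oxygen_solver,
    move_rule = x$move_rule,
    log_moves = x$log_moves, log_lifecycle = x$log_lifecycle
  )
}
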