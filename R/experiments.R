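# Canned in silico studies: the phenotype-mixture morphology panel, the
# proliferation/motility/switch perturbation trends, and the paired
# phenotypic-switch comparison.

#' Morphology panel across phenotype mixtures
#'
#' Runs one simulation per phenotype mixture at fixed kinetics (division age
#' 31 h, `D_c = 5e-9 cm^2/s` unless overridden), producing the spectrum of
#' morphologies from compact discs (high-adhesive mixtures) to scattered
#' starbursts (low-adhesive mixtures).
#'
#' @param mixtures a named list of phenotype sets (integer vectors in 0--7).
#' @param seed base seed; panel entry k uses `seed + k - 1`.
#' @param t_max_h simulation horizon per entry.
#' @param ... further overrides passed to [sim_config()].
#' @return a tibble with one row per mixture: final-state morphometrics plus
#'   the final `tumour_state` in a list-column `state`.
#' @export
mixture_panel <- function(mixtures, seed = 1L, t_max_h = 96, ...) {
  if (length(mixtures) == 0) abort("at least one mixture is required")
  if (is.null(names(mixtures))) {
    names(mixtures) <- vapply(mixtures, function(m) {
      paste(sort(m), collapse = "+")
    }, character(1))
  }
  rows <- purrr::imap(mixtures, function(ph, nm) {
    cfg <- sim_config(phenotypes = ph, T_p_h = 31,
                      phases = motility_phases(5e-9),
                      initial_radius_um = 140, t_max_h = t_max_h, ...)
    run <- sim_run(cfg, seed = seed + match(nm, names(mixtures)) - 1L)
    met <- morphology_metrics(run$state, "u87mg")
    mutate(met, mixture = nm, stop_reason = run$stop_reason, .before = 1) |>
      mutate(state = list(run$state))
  })
  bind_rows(rows)
}

#' Perturbation trend study
#'
#' Paired comparison of a baseline scenario against a rate perturbation:
#' `factor = "proliferation"` divides the division age `T_p` by `multiplier`
#' (faster cycling), `"motility"` multiplies every phase's `D_c`, and
#' `"switch"` turns on mitotic switching with `p_mut = 0.5`. Replicate pairs
#' share seeds (common random numbers), and metrics are compared at the
#' latest timepoint present in every run of both arms.
#'
#' @param config baseline `sim_config` (e.g. [config_u87mg()]).
#' @param factor which rate to perturb.
#' @param multiplier perturbation size (default doubling).
#' @param n_reps replicate pairs.
#' @param seed base seed.
#' @param alpha significance level for calling a direction.
#' @return a tibble with, per metric, the paired mean difference, one-sided
#'   Wilcoxon p-values (`p_greater`: perturbed > baseline) and a direction
#'   call among `"up"`, `"down"`, `"flat"`.
#' @export
trend_study <- function(config, factor = c("proliferation", "motility", "switch"),
                        multiplier = 2, n_reps = 10, seed = 1L, alpha = 0.05) {
  factor <- arg_match(factor)
  pert <- perturb_config(config, factor, multiplier)
  base_ens <- sim_replicates(config, n = n_reps, seed = seed)
  pert_ens <- sim_replicates(pert, n = n_reps, seed = seed)
  metrics <- c("n_cells", "invasive_radius_um", "compactness", "sparseness",
               paste0("freq_", 0:7))
  t_star <- latest_common_time(base_ens, pert_ens)
  b <- filter(base_ens$runs, .data$time_h == t_star) |> arrange(.data$replicate)
  p <- filter(pert_ens$runs, .data$time_h == t_star) |> arrange(.data$replicate)
  rows <- purrr::map(metrics, function(m) {
    d <- p[[m]] - b[[m]]
    if (all(is.na(d)) || all(abs(d) < 1e-12, na.rm = TRUE)) {
      return(tibble(metric = m, time_h = t_star,
                    baseline_mean = mean(b[[m]], na.rm = TRUE),
                    perturbed_mean = mean(p[[m]], na.rm = TRUE),
                    mean_diff = mean(d, na.rm = TRUE),
                    p_greater = 1, p_less = 1, direction = "flat"))
    }
    pg <- suppressWarnings(wilcox.test(d, alternative = "greater")$p.value)
    pl <- suppressWarnings(wilcox.test(d, alternative = "less")$p.value)
    dir <- if (pg < alpha) "up" else if (pl < alpha) "down" else "flat"
    tibble(metric = m, time_h = t_star,
           baseline_mean = mean(b[[m]], na.rm = TRUE),
           perturbed_mean = mean(p[[m]], na.rm = TRUE),
           mean_diff = mean(d, na.rm = TRUE),
           p_greater = pg, p_less = pl, direction = dir)
  })
  out <- bind_rows(rows)
  attr(out, "factor") <- factor
  attr(out, "multiplier") <- multiplier
  out
}

perturb_config <- function(config, factor, multiplier) {
  pert <- config
  if (factor == "proliferation") {
    pert$T_p_h <- config$T_p_h / multiplier
  } else if (factor == "motility") {
    pert$phases <- motility_phases(config$phases$D_c * multiplier,
                                   config$phases$t_end_h)
  } else {
    pert$p_mut <- 0.5
  }
  pert
}

latest_common_time <- function(...) {
  ensembles <- list(...)
  per_run_times <- purrr::map(ensembles, function(e) {
    split(e$runs$time_h, e$runs$replicate)
  })
  common <- Reduce(intersect, unlist(per_run_times, recursive = FALSE))
  if (length(common) == 0) abort("runs share no common timepoint")
  max(common)
}

#' Phenotypic-switch study
#'
#' Paired ensembles of a scenario with mitotic switching off (`p_mut = 0`)
#' and on (`p_mut`, default 0.5), sharing seeds. Reports the final common
#' timepoint's population, invasive radius and compactness per arm, and the
#' flattening of the phenotype frequencies (maximum absolute deviation from
#' the uniform frequency over the allowed set).
#'
#' @param config a `sim_config` scenario preset.
#' @param p_mut switch probability of the "on" arm.
#' @param n_reps replicate pairs.
#' @param seed base seed.
#' @return list with `comparison` (tibble, one row per arm) and the two
#'   `spheroid_ensemble`s (`off`, `on`).
#' @export
switch_study <- function(config, p_mut = 0.5, n_reps = 10, seed = 1L) {
  off_cfg <- config; off_cfg$p_mut <- 0
  on_cfg <- config; on_cfg$p_mut <- p_mut
  off <- sim_replicates(off_cfg, n = n_reps, seed = seed)
  on <- sim_replicates(on_cfg, n = n_reps, seed = seed)
  t_star <- latest_common_time(off, on)
  K <- length(config$phenotypes)
  fcols <- paste0("freq_", config$phenotypes)
  arm_row <- function(ens, arm) {
    fin <- filter(ens$runs, .data$time_h == t_star)
    fdev <- max(abs(colMeans(fin[fcols], na.rm = TRUE) - 1 / K))
    tibble(arm = arm, time_h = t_star,
           n_cells = mean(fin$n_cells),
           invasive_radius_um = mean(fin$invasive_radius_um),
           compactness = mean(fin$compactness),
           sparseness = mean(fin$sparseness),
           max_freq_deviation = fdev)
  }
  list(comparison = bind_rows(arm_row(off, "off"), arm_row(on, "on")),
       off = off, on = on)
}
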