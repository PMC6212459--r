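# broom-style tidiers for runs, ensembles and expansion fits.

#' Tidy a simulation run
#'
#' @param x a `spheroid_sim`.
#' @param ... unused.
#' @return long tibble with columns `time_h`, `metric`, `value`.
#' @export
tidy.spheroid_sim <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"time_h",
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.spheroid_sim
#' @return `glance.spheroid_sim()` returns a one-row run summary.
#' @export
glance.spheroid_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  tibble(cell_line = x$config$cell_line, seed = x$seed,
         t_end_h = x$state$time_h, stop_reason = x$stop_reason,
         n_cells = as.integer(last$n_cells),
         invasive_radius_um = last$invasive_radius_um,
         core_radius_um = last$core_radius_um,
         compactness = last$compactness, sparseness = last$sparseness,
         first_death_h = x$first_death_h,
         n_divisions = sum(x$events$event == "division"),
         n_deaths = sum(x$events$event == "death"))
}

#' Tidy a replicate ensemble
#'
#' @param x a `spheroid_ensemble`.
#' @param ... unused.
#' @return long tibble with per-timepoint ensemble `mean` and `sd` per metric.
#' @export
tidy.spheroid_ensemble <- function(x, ...) {
  s <- x$summary
  long <- tidyr::pivot_longer(s, -c("time_h", "n_runs"),
                              names_to = c("metric", "stat"),
                              names_pattern = "(.*)_(mean|sd)$")
  tidyr::pivot_wider(long, names_from = "stat", values_from = "value")
}

#' @rdname tidy.spheroid_ensemble
#' @export
glance.spheroid_ensemble <- function(x, ...) {
  tibble(cell_line = x$config$cell_line, n_replicates = length(x$seeds),
         seed_min = min(x$seeds), seed_max = max(x$seeds),
         median_first_death_h = median(x$first_death_h),
         n_stopped_edge = sum(x$stop_reason == "edge"))
}

#' Tidy an expansion-speed fit
#'
#' @param x an `expansion_fit` from [fit_expansion()].
#' @param ... unused.
#' @return per-term tibble of the underlying OLS fit (estimate, std.error,
#'   statistic, p.value).
#' @export
tidy.expansion_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.expansion_fit
#' @export
glance.expansion_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(metric = x$metric, window_start_h = x$window[1],
         window_end_h = x$window[2],
         speed_um_h = unname(coef(x$fit)[2]),
         r.squared = s$r.squared, sigma = s$sigma, nobs = x$n_points)
}
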