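# Scheduler: initialisation geometry, doubling kinetics, determinism,
# stopping rules, phase switching and replicate ensembles.

small_cfg <- function(...) {
  defaults <- list(geometry = tiny_geometry(61), phenotypes = c(0L, 1L, 6L, 7L),
                   initial_radius_um = 100, oxygen_solver = "frozen")
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("initialisation fills the lattice disc exactly", {
  # radius 0: just the centre site
  cfg0 <- small_cfg(initial_radius_um = 0, t_max_h = 0)
  w0 <- sim_init(cfg0, seed = 1)
  expect_equal(sum(w0$state$cells$alive), 1)
  expect_equal(w0$state$cells$i, w0$state$centre)

  # radius 140 um at h = 20 um: brute-force lattice-disc enumeration
  cfg <- sim_config(initial_radius_um = 140, t_max_h = 0)
  w <- sim_init(cfg, seed = 1)
  offs <- expand.grid(di = -10:10, dj = -10:10)
  n_expected <- sum(offs$di^2 + offs$dj^2 <= 7^2)
  expect_equal(sum(w$state$cells$alive), n_expected)
  lc <- live_cells(w$state)
  expect_setequal(paste(lc$i - w$state$centre, lc$j - w$state$centre),
                  paste(offs$di, offs$dj)[offs$di^2 + offs$dj^2 <= 49])
  expect_true(all(lc$dist_um <= 140))

  # ages uniform below each phenotype's division age; oxygen uniform at o_max
  expect_true(all(lc$age >= 0 & lc$age < 31))
  expect_true(all(w$oxygen$grid == cfg$oxygen$o_max))
  expect_equal(w$state$time_h, 0)

  # a mixture concentrated on one phenotype
  cfg7 <- small_cfg(phenotypes = 7L, t_max_h = 0)
  w7 <- sim_init(cfg7, seed = 2)
  expect_true(all(w7$state$cells$phenotype == 7L))
})

test_that("a step with no cells only advances oxygen and the clock", {
  cfg <- small_cfg(t_max_h = 0.8, oxygen_solver = "steady",
                   oxygen = oxygen_params(alpha_o = 0.02))
  w <- sim_init(cfg, seed = 1)
  w$state <- empty_state(cfg$geometry)
  w2 <- sim_step(w, cfg)
  expect_equal(w2$state$time_h, 0.8)
  expect_equal(nrow(w2$state$cells), 0)
  # decay pulls the interior strictly below o_max
  n <- cfg$geometry$n
  expect_lt(max(w2$oxygen$grid[2:(n - 1), 2:(n - 1)]), cfg$oxygen$o_max)
})

test_that("an immotile well-fed cell line doubles on the division clock", {
  cfg <- small_cfg(phenotypes = 7L, initial_radius_um = 0, T_p_h = 31,
                   phases = motility_phases(0), t_max_h = 126,
                   record_every_h = 0.8)
  run <- sim_run(cfg, seed = 5)
  m <- run$metrics
  # population is a power of two throughout the space-unlimited regime
  expect_true(all(log2(m$n_cells) %% 1 == 0))
  expect_gte(max(m$n_cells), 8)
  # doubling interval ~ T_p (quantised by t_r)
  jumps <- m$time_h[which(diff(m$n_cells) > 0) + 1]
  gaps <- diff(jumps)
  expect_true(all(abs(gaps - 31.2) <= 0.8 + 1e-9))
  # log-linear growth rate ~ ln 2 / T_p
  fit <- lm(log(n_cells) ~ time_h, data = m[m$time_h >= 31, ])
  expect_equal(unname(coef(fit)[2]), log(2) / 31, tolerance = 0.1)
})

test_that("identical seeds reproduce bitwise-identical series", {
  cfg <- small_cfg(t_max_h = 24)
  r1 <- sim_run(cfg, seed = 42)
  r2 <- sim_run(cfg, seed = 42)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$state$cells, r2$state$cells)
  r3 <- sim_run(cfg, seed = 43)
  expect_false(identical(r1$metrics, r3$metrics))
})

test_that("t_max = 0 yields only the initial metrics row", {
  run <- sim_run(small_cfg(t_max_h = 0), seed = 1)
  expect_equal(nrow(run$metrics), 1)
  expect_equal(run$metrics$time_h, 0)
  expect_equal(run$stop_reason, "t_max")
})

test_that("the edge rule stops runs before cells reach the border margin", {
  # fast dispersal on a small lattice triggers the edge stop
  cfg <- sim_config(geometry = tiny_geometry(41), phenotypes = 0L,
                    initial_radius_um = 60, phases = motility_phases(2e-8),
                    t_max_h = 216, edge_margin = 5, oxygen_solver = "frozen",
                    record_every_h = 0.8)
  run <- sim_run(cfg, seed = 9)
  expect_equal(run$stop_reason, "edge")
  expect_lt(run$state$time_h, 216)
  lc <- live_cells(run$state)
  border_dist <- pmin(lc$i - 1, 41 - lc$i, lc$j - 1, 41 - lc$j)
  expect_lt(min(border_dist), 5)
  # every state recorded before the final one respected the margin: re-run to
  # the penultimate recording and check
  cfg2 <- cfg
  cfg2$t_max_h <- run$state$time_h - cfg$t_r_h
  run2 <- sim_run(cfg2, seed = 9)
  lc2 <- live_cells(run2$state)
  expect_gte(min(pmin(lc2$i - 1, 41 - lc2$i, lc2$j - 1, 41 - lc2$j)), 5)
})

test_that("the motility kernel switches exactly at the phase boundary", {
  cfg <- small_cfg(phenotypes = 0L, initial_radius_um = 0,
                   T_p_h = 1e6,  # no divisions: a single walker
                   phases = motility_phases(c(0, 2e-8), c(24, Inf)),
                   t_max_h = 40, record_every_h = 8)
  run <- sim_run(cfg, seed = 3)
  m <- run$metrics
  expect_true(all(m$invasive_radius_um[m$time_h <= 24] == 0))
  expect_gt(max(m$invasive_radius_um[m$time_h > 24]), 0)
})

test_that("replicate ensembles summarise mean and spread per timepoint", {
  cfg <- small_cfg(t_max_h = 32, phases = motility_phases(1e-9))
  e1 <- sim_replicates(cfg, n = 1, seed = 7)
  single <- sim_run(cfg, seed = 7)
  expect_equal(e1$summary$invasive_radius_um_mean,
               single$metrics$invasive_radius_um)

  e8 <- sim_replicates(cfg, n = 8, seed = 21)
  s <- e8$summary
  late <- s[nrow(s), ]
  expect_gt(late$invasive_radius_um_sd, 0)
  expect_equal(late$n_runs, 8)

  # two disjoint seed blocks agree within Monte-Carlo error
  eA <- sim_replicates(cfg, n = 8, seed = 100)
  eB <- sim_replicates(cfg, n = 8, seed = 300)
  a <- eA$runs[eA$runs$time_h == 32, "invasive_radius_um", drop = TRUE]
  b <- eB$runs[eB$runs$time_h == 32, "invasive_radius_um", drop = TRUE]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
})

test_that("tidiers expose runs and ensembles as tibbles", {
  cfg <- small_cfg(t_max_h = 16)
  run <- sim_run(cfg, seed = 2)
  td <- tidy(run)
  expect_true(all(c("time_h", "metric", "value") %in% names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_cells, sum(run$state$cells$alive))

  ens <- sim_replicates(cfg, n = 2, seed = 2)
  te <- tidy(ens)
  expect_true(all(c("metric", "mean", "sd") %in% names(te)))
})
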