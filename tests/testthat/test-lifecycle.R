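# Lifecycle: age-gated division with space search and quiescence, mitotic
# phenotype switching applied to both daughters, hypoxic death.

lc_config <- function(...) {
  defaults <- list(geometry = tiny_geometry(21), phenotypes = 0:7,
                   T_p_h = 31, oxygen_solver = "frozen")
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("a ripe isolated cell divides; both daughters restart at age 0", {
  st <- state_with_cells(11, 11, phenotype = 4L, n_sites = 21, age = 31)
  cfg <- lc_config()
  set.seed(1)
  st2 <- attempt_division(st, 1L, cfg)
  expect_equal(sum(st2$cells$alive), 2)
  expect_equal(st2$cells$age, c(0, 0))
  expect_equal(st2$cells$phenotype, c(4L, 4L))  # p_mut = 0: inherited
  expect_false(any(st2$cells$quiescent))
  # daughter within the radius-2 Moore neighbourhood
  d <- st2$cells[2, ]
  expect_lte(max(abs(c(d$i, d$j) - 11)), 2)
  expect_equal(sum(st2$events$event == "division"), 1)
  expect_true(audit_consistency(st2))
})

test_that("an unripe cell only ages by t_r", {
  st <- state_with_cells(11, 11, phenotype = 4L, n_sites = 21, age = 10)
  st2 <- attempt_division(st, 1L, lc_config())
  expect_equal(sum(st2$cells$alive), 1)
  expect_equal(st2$cells$age, 10.8)
})

test_that("a ripe cell with a fully packed radius-2 neighbourhood goes quiescent", {
  ij <- expand.grid(i = 9:13, j = 9:13)  # 5x5 block: 24 occupied neighbours
  age <- ifelse(ij$i == 11 & ij$j == 11, 40, 0)
  st <- state_with_cells(ij$i, ij$j, phenotype = 7L, n_sites = 21, age = age)
  centre_id <- st$cells$id[st$cells$i == 11 & st$cells$j == 11]
  st2 <- attempt_division(st, centre_id, lc_config())
  row <- st2$cells[st2$cells$id == centre_id, ]
  expect_true(row$quiescent)
  expect_equal(sum(st2$cells$alive), 25)
  expect_equal(row$age, 40)  # age frozen in quiescence

  # rescue: vacate one site within radius 2 -> immediate division next turn
  vac <- st2$cells$id[st2$cells$i == 9 & st2$cells$j == 9]
  st2$occ[9, 9] <- 0L
  st2$cells$alive[st2$cells$id == vac] <- FALSE
  set.seed(2)
  st3 <- attempt_division(st2, centre_id, lc_config())
  expect_equal(sum(st3$cells$alive), 25)  # 24 survivors + daughter
  row3 <- st3$cells[st3$cells$id == centre_id, ]
  expect_false(row3$quiescent)
  expect_equal(row3$age, 0)
  expect_equal(st3$occ[9, 9], max(st3$cells$id))
})

test_that("the mitotic switch draws uniformly and is applied to both daughters", {
  expect_equal(apply_phenotype_switch(3L, p_mut = 0, target_set = 0:7), 3L)

  set.seed(11)
  draws <- replicate(8000, apply_phenotype_switch(0L, 1, c(0L, 1L, 6L, 7L)))
  tab <- table(factor(draws, levels = c(0, 1, 6, 7)))
  expect_gt(chisq.test(tab, p = rep(0.25, 4))$p.value, 1e-3)

  # long-run chain with p_mut = 0.5 has the uniform stationary distribution
  # (thinned to break the stay-put autocorrelation)
  set.seed(12)
  ph <- 2L
  visits <- integer(6)
  for (k in 1:20000) {
    ph <- apply_phenotype_switch(ph, 0.5, 2:7)
    if (k %% 10 == 0) visits[ph - 1] <- visits[ph - 1] + 1
  }
  expect_gt(chisq.test(visits, p = rep(1 / 6, 6))$p.value, 1e-3)

  expect_error(apply_phenotype_switch(3L, 0.5, integer(0)), "non-empty")

  # a fired switch reassigns parent and daughter alike
  st <- state_with_cells(11, 11, phenotype = 5L, n_sites = 21, age = 40)
  cfg <- lc_config(phenotypes = 3L, p_mut = 1)
  st2 <- attempt_division(st, 1L, cfg)
  expect_equal(st2$cells$phenotype, c(3L, 3L))
  expect_equal(sum(st2$events$event == "switch"), 1)
})

test_that("hypoxic death frees sites and only strikes below-threshold cells", {
  st <- state_with_cells(c(5, 11), c(5, 11), phenotype = 4L, n_sites = 21)
  f <- oxygen_field(tiny_geometry(21), oxygen_params(o_deadly = 0.1))

  same <- apply_hypoxic_death(st, f)
  expect_equal(sum(same$cells$alive), 2)

  f$grid[5, 5] <- 0.02
  st2 <- apply_hypoxic_death(st, f)
  expect_equal(sum(st2$cells$alive), 1)
  expect_equal(st2$occ[5, 5], 0L)
  expect_false(st2$cells$alive[st2$cells$i == 5 & st2$cells$j == 5])
  expect_equal(sum(st2$events$event == "death"), 1)
  expect_true(audit_consistency(st2))

  # the freed site is available again for a daughter
  neighbour <- state_with_cells(c(5, 6), c(5, 5), phenotype = 7L,
                                n_sites = 21, age = c(0, 40))
  f2 <- oxygen_field(tiny_geometry(21), oxygen_params(o_deadly = 0.1))
  f2$grid[5, 5] <- 0.01
  neighbour <- apply_hypoxic_death(neighbour, f2)
  set.seed(3)
  after <- attempt_division(neighbour, 2L, lc_config())
  expect_equal(sum(after$cells$alive), 2)
})

test_that("a static packed disc under consumption dies first at the centre", {
  n <- 41
  disc <- phantom_disc(radius_um = 240, h_um = 20, n = n)
  f <- oxygen_field(tiny_geometry(n), oxygen_params(gamma_o = 0.2))
  dead <- integer(0)
  for (k in 1:80) {
    f <- oxygen_advance(f, disc$occ, duration_h = 0.5)
    st <- apply_hypoxic_death(disc, f)
    dead <- st$cells$id[!st$cells$alive]
    if (length(dead)) break
  }
  expect_gt(length(dead), 0)
  c0 <- disc$centre
  d <- sqrt((disc$cells$i[dead] - c0)^2 + (disc$cells$j[dead] - c0)^2)
  expect_true(any(d < 1e-9))  # the centremost cell is in the first casualties
  expect_lte(max(d), 6)
})
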