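# Movement: kernel algebra, neighbour counting with self-exclusion,
# admissibility, destination distribution and the free-walker MSD law.

test_that("kernel algebra follows the diffusion discretisation", {
  k0 <- move_kernel(0)
  expect_equal(k0$p_move, 0)
  expect_equal(k0$n_substeps, 1L)

  # substep bound h^2/(4 D_c) for D_c = 5e-9 cm2/s at h = 20 um is 200 s
  expect_equal((20e-4)^2 / (4 * 5e-9), 200)
  k <- move_kernel(5e-9, h_um = 20, t_r_h = 0.8)
  expect_equal(k$n_substeps, ceiling(2880 / 200))  # 15
  expect_equal(k$k_s, 2880 / 15)                   # 192 s
  expect_equal(k$p_move, 4 * 5e-9 * 192 / (20e-4)^2)  # 0.96
  expect_equal(k$p_move, 0.96, tolerance = 1e-12)
  expect_lte(k$p_move, 1)
  expect_equal(k$n_substeps * k$k_s, 2880)

  expect_error(move_kernel(-1), "positive|>= 0")
})

test_that("occupied-neighbour counts exclude the cell under study", {
  st <- state_with_cells(6, 6, n_sites = 11)  # isolated cell
  expect_equal(occupied_neighbours(st, 6, 7), 1)
  expect_equal(occupied_neighbours(st, 6, 7, exclude = 1L), 0)
  expect_equal(occupied_neighbours(st, 9, 9), 0)

  # fully surrounded site
  ij <- expand.grid(i = 5:7, j = 5:7)
  full <- state_with_cells(ij$i, ij$j, n_sites = 11)
  expect_equal(occupied_neighbours(full, 6, 6), 8)
  centre_id <- full$cells$id[full$cells$i == 6 & full$cells$j == 6]
  # a site adjacent to the block, excluding the mover at (6,5)
  mover <- full$cells$id[full$cells$i == 6 & full$cells$j == 5]
  expect_equal(occupied_neighbours(full, 6, 4, exclude = mover), 2)
  expect_error(occupied_neighbours(full, 0, 3), "outside")
})

test_that("wall configuration admits exactly the three left positions for preference 0", {
  w <- wall_state(mover_pref = 0L)
  c <- w$centre
  # the three left empty sites each score 0 occupied neighbours for the mover
  for (di in -1:1) {
    expect_equal(occupied_neighbours(w$state, c + di, c - 1, exclude = w$mover), 0)
  }
  dest <- admissible_destinations(w$state, w$mover)
  expect_equal(nrow(dest), 3)
  expect_setequal(paste(dest$i, dest$j), paste(c + (-1:1), c - 1))
})

test_that("admissible sets are empty when no destination can match", {
  # all 8 neighbours occupied: no empty adjacent site at all
  ij <- expand.grid(i = 5:7, j = 5:7)
  full <- state_with_cells(ij$i, ij$j, n_sites = 11)
  centre_id <- full$cells$id[full$cells$i == 6 & full$cells$j == 6]
  expect_equal(nrow(admissible_destinations(full, centre_id)), 0)

  # preference 7 in empty space: no site can see 7 occupied neighbours
  lone <- state_with_cells(6, 6, phenotype = 7L, n_sites = 11)
  expect_equal(nrow(admissible_destinations(lone, 1L)), 0)
})

test_that("an isolated preference-0 cell moves uniformly over the 8 neighbours", {
  kern <- list(D_c = NA, k_s = NA, n_substeps = 1L, p_move = 1)
  counts_prop <- counts_ren <- integer(8)
  offsets <- expand.grid(di = -1:1, dj = -1:1)
  offsets <- offsets[!(offsets$di == 0 & offsets$dj == 0), ]
  set.seed(99)
  n_draw <- 4000
  for (rule in c("proposal", "renormalised")) {
    counts <- integer(8)
    for (r in seq_len(n_draw)) {
      st <- state_with_cells(6, 6, phenotype = 0L, n_sites = 11)
      st2 <- attempt_move(st, 1L, kern, move_rule = rule)
      lc <- st2$cells[1, ]
      k <- which(offsets$di == lc$i - 6 & offsets$dj == lc$j - 6)
      expect_length(k, 1)  # always moved (p_move = 1, all 8 admissible)
      counts[k] <- counts[k] + 1
    }
    p <- chisq.test(counts, p = rep(1 / 8, 8))$p.value
    expect_gt(p, 1e-3)
  }
})

test_that("free-walker mean squared displacement matches the closed form", {
  # E[step^2] per substep = p_move * (4 h^2 + 4 * 2 h^2) / 8 = 1.5 p h^2,
  # so after n substeps the MSD is n * 1.5 * p_move * h^2 exactly.
  h <- 20
  nsub <- 30L
  p_move <- 0.5
  kern <- list(D_c = NA, k_s = NA, n_substeps = nsub, p_move = p_move)
  n_walk <- 1000
  set.seed(4242)
  d2 <- numeric(n_walk)
  for (w in seq_len(n_walk)) {
    st <- state_with_cells(41, 41, phenotype = 0L, n_sites = 81)
    st2 <- attempt_move(st, 1L, kern)
    lc <- st2$cells[1, ]
    d2[w] <- ((lc$i - 41)^2 + (lc$j - 41)^2) * h^2
  }
  expected <- nsub * 1.5 * p_move * h^2
  se <- sd(d2) / sqrt(n_walk)
  expect_lt(abs(mean(d2) - expected), 3 * se)
})

test_that("moves preserve exclusion and respect immotility", {
  # never lands on an occupied site
  set.seed(5)
  st <- random_scatter(80, n_sites = 21, seed = 5)
  kern <- list(D_c = NA, k_s = NA, n_substeps = 10L, p_move = 1)
  for (id in sample(st$cells$id, 20)) {
    st <- attempt_move(st, id, kern)
    expect_true(audit_consistency(st))
  }

  # p_move = 0 leaves the position untouched
  st0 <- state_with_cells(6, 6, phenotype = 0L, n_sites = 11)
  st1 <- attempt_move(st0, 1L, move_kernel(0))
  expect_equal(st1$cells$i, st0$cells$i)
  expect_equal(st1$cells$j, st0$cells$j)
})

test_that("preference-7 cells strictly inside a packed disc never move", {
  disc <- phantom_disc(radius_um = 120, h_um = 20, n = 25, phenotype = 7L)
  inner <- live_cells(disc) |> dplyr::filter(.data$dist_um <= 80)
  kern <- list(D_c = NA, k_s = NA, n_substeps = 50L, p_move = 1)
  st <- disc
  set.seed(8)
  for (id in inner$id) st <- attempt_move(st, id, kern)
  after <- st$cells[match(inner$id, st$cells$id), ]
  expect_equal(after$i, inner$i)
  expect_equal(after$j, inner$j)
})
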