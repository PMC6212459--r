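# Oxygen reaction-diffusion: explicit transient scheme, steady-state
# relaxation, hypoxia predicate, maximum principle and monotonicity.

ox_par <- function(...) oxygen_params(...)

empty_occ <- function(n) matrix(0L, n, n)

test_that("a uniform field with no cells and no decay is a steady state", {
  f <- oxygen_field(tiny_geometry(21), ox_par(alpha_o = 0, gamma_o = 0.01))
  adv <- oxygen_advance(f, empty_occ(21), duration_h = 2)
  expect_equal(adv$grid, f$grid, tolerance = 1e-12)
  st <- oxygen_steady(f, empty_occ(21))
  expect_equal(st$grid, f$grid, tolerance = 1e-9)
})

test_that("transient and relaxation solvers agree with a direct linear solve", {
  n <- 21
  p <- ox_par(D_o = 1e-5, alpha_o = 0.02, gamma_o = 0.05)
  occ <- empty_occ(n)
  occ[9:13, 9:13] <- 1L  # small occupied block consumes oxygen
  truth <- oracle_oxygen_steady(n, occ, p$D_o, p$alpha_o, p$gamma_o,
                                p$o_max, 20e-4)

  f <- oxygen_field(tiny_geometry(n), p)
  relax <- oxygen_steady(f, occ)
  expect_equal(relax$grid, truth, tolerance = 1e-6)

  # explicit integration approaches the same steady state monotonically
  # (the grid relaxes over a few seconds, so probe with 1 s increments)
  prev <- f
  deviation <- numeric(4)
  for (k in 1:4) {
    nxt <- oxygen_advance(prev, occ, duration_h = 1 / 3600)
    expect_true(all(nxt$grid[2:(n - 1), 2:(n - 1)] <=
                      prev$grid[2:(n - 1), 2:(n - 1)] + 1e-12))
    deviation[k] <- max(abs(nxt$grid - truth))
    prev <- nxt
  }
  expect_true(all(diff(deviation) < 1e-10))
  expect_lt(deviation[4], deviation[1])
  long <- oxygen_advance(f, occ, duration_h = 12)
  expect_equal(long$grid, truth, tolerance = 1e-4)
})

test_that("1D strip steady profile matches the cosh closed form", {
  # reflecting rows turn a thin strip into the 1D problem
  #   D o'' = alpha o, o(+-X) = o_max  =>  o = o_max cosh(x/l)/cosh(X/l)
  nc <- 41
  p <- ox_par(D_o = 1e-5, alpha_o = 0.1, gamma_o = 0)
  f <- oxygen_field(NULL, p, dim = c(5, nc))
  f$h_um <- 20
  adv <- oxygen_advance(f, matrix(0L, 5, nc), duration_h = 6,
                        boundary = "reflect_rows")
  h_cm <- 20e-4
  l <- sqrt(p$D_o / p$alpha_o)
  x <- (seq_len(nc) - (nc + 1) / 2) * h_cm
  X <- (nc - 1) / 2 * h_cm
  analytic <- p$o_max * cosh(x / l) / cosh(X / l)
  expect_equal(adv$grid[3, ], analytic, tolerance = 0.02)
  # rows are uniform (true 1D behaviour)
  expect_equal(adv$grid[1, ], adv$grid[3, ], tolerance = 1e-10)
})

test_that("hypoxic_sites returns exactly the sites strictly below threshold", {
  f <- oxygen_field(tiny_geometry(11), ox_par(o_deadly = 0.1))
  expect_equal(nrow(hypoxic_sites(f)), 0)
  f$grid[4, 7] <- 0.05
  hs <- hypoxic_sites(f)
  expect_equal(nrow(hs), 1)
  expect_equal(c(hs$i, hs$j), c(4, 7))
  f$grid[5, 5] <- 0.1  # boundary case: equality is not hypoxic
  expect_equal(nrow(hypoxic_sites(f)), 1)
})

test_that("a consuming disc becomes hypoxic from the centre outward", {
  n <- 51
  geom <- tiny_geometry(n)
  disc <- phantom_disc(radius_um = 300, h_um = 20, n = n)
  p <- ox_par(gamma_o = 0.2, o_deadly = 0.1)
  f <- oxygen_field(geom, p)
  f <- oxygen_steady(f, disc$occ)
  c0 <- disc$centre
  expect_equal(unname(which(f$grid == min(f$grid), arr.ind = TRUE)[1, ]),
               c(c0, c0))
  hs <- hypoxic_sites(f)
  expect_gt(nrow(hs), 0)
  # radially monotone: the hypoxic set contains the centre and every hypoxic
  # site is nearer the centre than every non-hypoxic occupied site's maximum
  expect_true(any(hs$i == c0 & hs$j == c0))
  d_hyp <- sqrt((hs$i - c0)^2 + (hs$j - c0)^2)
  expect_true(max(d_hyp) <= 300 / 20)
})

test_that("maximum principle and cell-monotonicity hold", {
  n <- 21
  p <- ox_par(alpha_o = 0.01, gamma_o = 0.08)
  for (seed in 1:4) {
    set.seed(seed)
    occ <- matrix(rbinom(n^2, 1, 0.2), n, n)
    f <- oxygen_field(tiny_geometry(n), p)
    adv <- oxygen_advance(f, occ, duration_h = runif(1, 0.1, 2))
    expect_gte(min(adv$grid), 0)
    expect_lte(max(adv$grid), p$o_max)

    # adding cells never increases the field anywhere
    occ2 <- occ
    empty_idx <- which(occ2 == 0)
    occ2[sample(empty_idx, 20)] <- 1L
    adv2 <- oxygen_advance(f, occ2, duration_h = 0.5)
    adv1 <- oxygen_advance(f, occ, duration_h = 0.5)
    expect_true(all(adv2$grid <= adv1$grid + 1e-12))
  }
})

test_that("with no reaction the interior relaxes back to the boundary value", {
  n <- 21
  p <- ox_par(alpha_o = 0, gamma_o = 0)
  f <- oxygen_field(tiny_geometry(n), p)
  set.seed(3)
  f$grid[2:(n - 1), 2:(n - 1)] <- runif((n - 2)^2, 0.2, 1)
  dev0 <- sum(abs(f$grid - p$o_max))
  a1 <- oxygen_advance(f, empty_occ(n), duration_h = 0.5)
  a2 <- oxygen_advance(a1, empty_occ(n), duration_h = 4)
  expect_lt(sum(abs(a1$grid - p$o_max)), dev0)
  expect_lt(max(abs(a2$grid - p$o_max)), 1e-3)
})

test_that("dimension mismatches are rejected", {
  f <- oxygen_field(tiny_geometry(11))
  expect_error(oxygen_advance(f, matrix(0L, 5, 5), 1), "dimensions")
  expect_error(oxygen_steady(f, matrix(0L, 5, 5)), "dimensions")
})
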