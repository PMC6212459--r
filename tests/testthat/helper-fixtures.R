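# Shared fixtures: tiny lattices, hand-built cell configurations and
# brute-force oracles used across the test files.

tiny_geometry <- function(n_sites = 21, h_um = 20) {
  lattice_geometry(L_mm = n_sites * h_um / 1000, h_um = h_um)
}

# A state with cells at explicit (i, j) positions on an n x n lattice.
state_with_cells <- function(i, j, phenotype = 7L, n_sites = 21, age = 0) {
  place_cells(empty_state(tiny_geometry(n_sites)), i, j, phenotype, age)
}

# The three-cells-to-the-right configuration: a mover with a vertical wall of
# cells on its right. The three left-hand sites see no occupied neighbour
# other than the mover itself, so they (and only they) are admissible for a
# preference-0 cell.
wall_state <- function(mover_pref = 0L, n_sites = 11) {
  c <- (n_sites + 1) %/% 2
  st <- state_with_cells(c(c, c - 1, c, c + 1), c(c, c + 1, c + 1, c + 1),
                         phenotype = c(mover_pref, 7L, 7L, 7L),
                         n_sites = n_sites)
  list(state = st, mover = 1L, centre = c)
}

# Scatter k cells uniformly over distinct random sites.
random_scatter <- function(k, n_sites = 41, seed = 1) {
  set.seed(seed)
  idx <- sample.int(n_sites^2, k)
  i <- (idx - 1) %% n_sites + 1
  j <- (idx - 1) %/% n_sites + 1
  state_with_cells(i, j, phenotype = sample(0:7, k, replace = TRUE),
                   n_sites = n_sites)
}

# Brute-force morphometric oracles (independent of the package internals).
oracle_invasive_radius <- function(state) {
  lc <- state$cells[state$cells$alive, ]
  c0 <- state$centre
  h <- state$geometry$h_um
  max(sqrt((lc$i - c0)^2 + (lc$j - c0)^2)) * h
}

oracle_compactness <- function(state) {
  occ <- state$occ != 0
  n <- nrow(occ)
  lc <- state$cells[state$cells$alive, ]
  counts <- vapply(seq_len(nrow(lc)), function(k) {
    i <- lc$i[k]; j <- lc$j[k]
    tot <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && occ[ii, jj]) tot <- tot + 1L
    }
    tot
  }, integer(1))
  mean(counts / 8)
}

oracle_sparseness <- function(state) {
  lc <- state$cells[state$cells$alive, ]
  if (nrow(lc) < 2) return(NA_real_)
  d <- as.matrix(dist(cbind(lc$i, lc$j)))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Direct sparse steady-state solve of D lap(o) = (alpha + gamma c) o with
# Dirichlet o_max boundaries on a small grid (independent linear-algebra
# oracle for the relaxation solvers).
oracle_oxygen_steady <- function(n, occ, D_o, alpha_o, gamma_o, o_max, h_cm) {
  interior <- as.matrix(expand.grid(i = 2:(n - 1), j = 2:(n - 1)))
  id <- function(i, j) (j - 2) * (n - 2) + (i - 1)
  m <- nrow(interior)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(m)
  Dh2 <- D_o / h_cm^2
  for (r in seq_len(m)) {
    i <- interior[r, 1]; j <- interior[r, 2]
    sig <- alpha_o + if (occ[i, j] > 0) gamma_o else 0
    trip_i <- c(trip_i, r); trip_j <- c(trip_j, r)
    trip_x <- c(trip_x, 4 * Dh2 + sig)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii == 1 || ii == n || jj == 1 || jj == n) {
        rhs[r] <- rhs[r] + Dh2 * o_max
      } else {
        trip_i <- c(trip_i, r); trip_j <- c(trip_j, id(ii, jj))
        trip_x <- c(trip_x, -Dh2)
      }
    }
  }
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(m, m))
  sol <- as.numeric(Matrix::solve(A, rhs))
  g <- matrix(o_max, n, n)
  g[interior] <- sol
  g
}
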