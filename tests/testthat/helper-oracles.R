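# Shared fixtures and independent oracles for the test suite.

# Friction surface built directly from a speed matrix (km/h, 0 = blocked).
make_friction <- function(speed, cell_size = 1000,
                          scenario = scenario_spec("walk")) {
  g <- grid_spec(nrow(speed), ncol(speed), cell_size)
  structure(list(grid = g, speed = speed, passable = speed > 0,
                 scenario = scenario),
            class = "friction_surface")
}

# Facility set at the centers of given (row, col) cells of a grid.
facilities_at_cells <- function(grid, cells,
                                level = rep("HC2", nrow(cells))) {
  cc <- cell_centers(grid)
  facility_set(cc$x[cells], cc$y[cells], level)
}

# Independent shortest-path oracle: Bellman-Ford-style relaxation over the
# 8-connected grid graph with the same half-cell edge-cost rule, iterated
# to a fixed point. Exact, and algorithmically independent of the heap
# Dijkstra under test.
relaxation_tt <- function(speed, cell_size, source_cells) {
  nr <- nrow(speed); nc <- ncol(speed)
  d_km <- cell_size / 1000
  dist <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(source_cells)))
    dist[source_cells[i, 1], source_cells[i, 2]] <- 0
  steps <- expand.grid(dr = -1:1, dc = -1:1)
  steps <- steps[!(steps$dr == 0 & steps$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!(speed[r, c] > 0)) next
      for (s in seq_len(nrow(steps))) {
        r2 <- r + steps$dr[s]; c2 <- c + steps$dc[s]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!(speed[r2, c2] > 0)) next
        len <- d_km * if (steps$dr[s] != 0 && steps$dc[s] != 0) sqrt(2) else 1
        t <- 60 * (len / 2) * (1 / speed[r, c] + 1 / speed[r2, c2])
        if (dist[r2, c2] + t < dist[r, c] - 1e-12) {
          dist[r, c] <- dist[r2, c2] + t
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist
}

# Exhaustive oracle: minimum travel time over every simple path, tiny
# grids only.
enumeration_tt <- function(speed, cell_size, source_cells) {
  nr <- nrow(speed); nc <- ncol(speed)
  d_km <- cell_size / 1000
  id <- function(r, c) (c - 1L) * nr + r
  pass <- speed > 0
  best <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(source_cells)))
    best[source_cells[i, 1], source_cells[i, 2]] <- 0
  dfs <- function(r, c, acc, visited) {
    if (acc < best[r, c]) best[r, c] <<- acc
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!pass[r2, c2] || visited[id(r2, c2)]) next
      len <- d_km * if (dr != 0 && dc != 0) sqrt(2) else 1
      t <- 60 * (len / 2) * (1 / speed[r, c] + 1 / speed[r2, c2])
      v2 <- visited; v2[id(r2, c2)] <- TRUE
      dfs(r2, c2, acc + t, v2)
    }
  }
  for (i in seq_len(nrow(source_cells))) {
    r <- source_cells[i, 1]; c <- source_cells[i, 2]
    v <- rep(FALSE, nr * nc); v[id(r, c)] <- TRUE
    dfs(r, c, 0, v)
  }
  best
}

# Dense-matrix Gi* oracle: full binary W with self-term, matrix algebra
# throughout — an independent code path from the adjacency-list version.
gi_star_oracle <- function(values, weights) {
  n <- weights$n
  W <- diag(n)
  for (i in seq_len(n)) W[i, weights$neighbors[[i]]] <- 1
  x <- values
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  Wi <- rowSums(W)
  S1 <- rowSums(W^2)
  num <- as.vector(W %*% x) - xbar * Wi
  den <- S * sqrt((n * S1 - Wi^2) / (n - 1))
  z <- num / den
  z[Wi >= n] <- NA_real_   # whole-study neighborhood: undefined
  z
}

# Zone label raster forming a regular nz_r x nz_c lattice of square zones.
lattice_zones <- function(nz_r, nz_c, cells_per_zone = 2L) {
  zr <- rep(seq_len(nz_r), each = cells_per_zone)
  zc <- rep(seq_len(nz_c), each = cells_per_zone)
  outer(zr, zc, function(a, b) (a - 1L) * nz_c + b)
}

# Small scene shared across tests (cached per session).
test_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_scene(7, grid_spec(50, 50, 1000),
                               scene_params(n_clusters = 8, n_parishes = 50,
                                            n_subregions = 5))
    cache
  }
})
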