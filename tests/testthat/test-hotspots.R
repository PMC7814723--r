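test_that("queen contiguity matches lattice hand counts and is cumulative", {
  z <- lattice_zones(3, 3)                 # 3x3 lattice of square zones
  w1 <- queen_weights(z, 1)
  expect_equal(w1$neighbors[[5]], c(1:4, 6:9))          # center: all 8
  expect_equal(w1$neighbors[[1]], c(2, 4, 5))           # corner: 3
  w2 <- queen_weights(z, 2)
  expect_equal(w2$neighbors[[1]], c(2:9))               # corner order 2: all
  for (i in seq_len(9))
    expect_true(all(w1$neighbors[[i]] %in% w2$neighbors[[i]]))
  # exclusive variant keeps only the outer ring
  w2x <- queen_weights(z, 2, cumulative = FALSE)
  expect_equal(w2x$neighbors[[1]], setdiff(2:9, c(2, 4, 5)))
})

test_that("gi_star matches the hand-computed path-graph values", {
  z <- lattice_zones(1, 4)                 # 4-zone path
  w <- queen_weights(z, 1)
  g <- gi_star(c(10, 0, 0, 0), w)
  # n = 4, xbar = 2.5, S = sqrt(18.75); zone 1: W = 2, num = 10 - 5 = 5,
  # den = S * sqrt((8 - 4)/3) -> z = 1 exactly
  expect_equal(g[1], 1.0, tolerance = 1e-12)
  expect_equal(g[2], 2.5 / sqrt(18.75), tolerance = 1e-12)
  expect_error(gi_star(rep(3, 4), w), "variance")
})

test_that("gi_star agrees with the dense-matrix oracle on random instances", {
  set.seed(99)
  for (rep in 1:30) {
    nzr <- sample(4:7, 1); nzc <- sample(4:7, 1)
    z <- lattice_zones(nzr, nzc)
    vals <- rnorm(nzr * nzc)
    for (ord in 1:3) {
      w <- queen_weights(z, ord)
      expect_equal(gi_star(vals, w), gi_star_oracle(vals, w),
                   tolerance = 1e-9)
    }
  }
})

test_that("permutation p-values are deterministic, valid and calibrated", {
  z <- lattice_zones(6, 6)
  w <- queen_weights(z, 1)
  set.seed(5)
  vals <- rnorm(36)
  p1 <- permutation_p(vals, w, n_perm = 999, seed = 11)
  p2 <- permutation_p(vals, w, n_perm = 999, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  expect_error(permutation_p(vals, w, n_perm = 99), "999")

  # under spatial randomness p is roughly uniform: the rejection rate at
  # 0.05 stays near nominal across many zones and replicates
  set.seed(21)
  hits <- unlist(lapply(1:12, function(i)
    permutation_p(rnorm(36), w, n_perm = 999, seed = i) <= 0.05))
  expect_gt(mean(hits), 0.05 - 0.03)
  expect_lt(mean(hits), 0.05 + 0.03)
})

test_that("the monotone multi-order rule labels as specified", {
  # planted 3x3 high block in an 8x8 zone lattice
  z <- lattice_zones(8, 8)
  set.seed(4)
  vals <- rnorm(64)
  block <- as.vector(outer(3:5, (3:5 - 1) * 8, "+"))
  vals[block] <- vals[block] + 5
  res <- multi_order_clusters(vals, z, alpha = 0.01, n_perm = 999, seed = 2)
  expect_true(all(res$label[res$label != "none"] %in% c("high", "low")))
  expect_true(any(res$label[block] == "high"))
  # never labeled at an order without significance there
  for (i in which(!is.na(res$order))) {
    k <- res$order[i]
    expect_lte(res[[paste0("p", k)]][i], 0.01)
    if (k > 1)
      expect_true(all(abs(res[[paste0("z", k)]][i]) >
                        abs(sapply(seq_len(k - 1), function(j)
                          res[[paste0("z", j)]][i]))))
  }

  # a zone significant at order 1 whose |z| shrinks afterwards stays order 1
  dec <- which(res$order == 1L)
  if (length(dec))
    expect_true(all(abs(res$z2[dec]) <= abs(res$z1[dec]) |
                      res$p2[dec] > 0.01))

  # null case: no significant zone -> all labels none
  res0 <- multi_order_clusters(rep(c(1, 2), 32), z, alpha = 1e-6,
                               n_perm = 999, seed = 3)
  expect_true(all(res0$label == "none"))
})

test_that("zonal means follow hand arithmetic and flag empty zones", {
  g <- grid_spec(2, 2, 100)
  tt <- structure(list(grid = g,
                       minutes = matrix(c(10, 30, 20, 40), 2, 2),
                       provenance = list(level = "HC2", mode = "walk",
                                         multiplier = 1)),
                  class = "travel_time_surface")
  zones <- rbind(c(1L, 1L), c(2L, 2L))   # top row zone 1, bottom zone 2
  expect_equal(zonal_mean(tt, zones), c(15, 35))

  # constant raster -> the constant everywhere
  tt$minutes <- matrix(7, 2, 2)
  expect_equal(zonal_mean(tt, zones), c(7, 7))

  # fully unreachable zone -> NA with warning, then excluded from Gi*
  tt$minutes <- rbind(c(5, 5), c(Inf, Inf))
  expect_warning(zm <- zonal_mean(tt, zones), "no finite")
  expect_true(is.na(zm[2]))
})

test_that("zone summaries expose the bubble-plot table", {
  s <- test_scene()
  tt <- scene_travel_time(s, "HC2", scenario_spec("walk"))
  zs <- suppressWarnings(zone_summary(s, tt))
  expect_equal(nrow(zs), s$params$n_parishes)
  expect_true(all(zs$poverty >= 0 & zs$poverty <= 1))
  expect_equal(sum(zs$population), sum(s$population), tolerance = 1e-9)
})
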