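test_that("eligibility unions higher tiers into lower-level analyses", {
  set.seed(1)
  n <- c(40, 20, 8, 4, 2, 1)
  fs <- facility_set(runif(sum(n)), runif(sum(n)),
                     rep(facility_levels, n))
  expect_equal(nrow(eligible_facilities(fs, "NRH")), 1L)
  expect_true(all(eligible_facilities(fs, "NRH")$level == "NRH"))
  expect_equal(nrow(eligible_facilities(fs, "HC2")), sum(n))
  expect_equal(nrow(eligible_facilities(fs, "HC4")), 15L)
})

test_that("travel time matches hand-computed neighbor costs", {
  sp <- matrix(6, 2, 2)                 # 100 m cells, all 6 km/h
  fr <- make_friction(sp, cell_size = 100)
  fac <- facilities_at_cells(fr$grid, cbind(1, 1))
  tt <- compute_travel_time(fr, fac)
  expect_equal(tt$minutes[1, 1], 0)                       # source identity
  expect_equal(tt$minutes[1, 2], 1.0)                     # orthogonal step
  expect_equal(tt$minutes[2, 2], sqrt(2), tolerance = 1e-12)  # diagonal
})

test_that("cells cut off by an impassable ring are unreachable", {
  sp <- matrix(5, 5, 5)
  sp[2:4, 2:4] <- 0
  sp[3, 3] <- 5                         # island inside the ring
  fr <- make_friction(sp, 100)
  tt <- compute_travel_time(fr, facilities_at_cells(fr$grid, cbind(1, 1)))
  expect_identical(tt$minutes[3, 3], Inf)
  expect_true(all(is.finite(tt$minutes[sp > 0 &
                                         !(row(sp) == 3 & col(sp) == 3)])))
})

test_that("dijkstra equals the exhaustive path-enumeration oracle on 3x3", {
  set.seed(42)
  for (rep in 1:25) {
    sp <- matrix(sample(c(0, 2, 5, 12), 9, replace = TRUE,
                        prob = c(0.2, 0.3, 0.3, 0.2)), 3, 3)
    sp[2, 1] <- 5                       # keep the source passable
    fr <- make_friction(sp, 100)
    tt <- compute_travel_time(fr, facilities_at_cells(fr$grid, cbind(2, 1)),
                              snap_radius = 0L)
    oracle <- enumeration_tt(sp, 100, cbind(2, 1))
    expect_equal(tt$minutes, oracle, tolerance = 1e-12)
  }
})

test_that("facilities on impassable cells snap within the radius or error", {
  sp <- matrix(5, 5, 5); sp[3, 3] <- 0
  fr <- make_friction(sp, 100)
  fac <- facilities_at_cells(fr$grid, cbind(3, 3))
  tt <- compute_travel_time(fr, fac)          # snaps to a neighbor
  expect_equal(sum(tt$minutes == 0), 1L)
  sp2 <- matrix(0, 9, 9); sp2[1, 1] <- 5
  fr2 <- make_friction(sp2, 100)
  expect_error(compute_travel_time(fr2, facilities_at_cells(fr2$grid,
                                                            cbind(5, 5))),
               "no passable cell")
  expect_error(compute_travel_time(fr, fac[0, ]), "empty source")
})

test_that("speed scaling, added facilities and tier order are monotone", {
  s <- test_scene()
  rr <- rasterize_roads(s$roads, s$grid)
  f1 <- build_friction(s$landcover, rr, s$barriers,
                       scenario_spec("walk", 1.0), s$grid)
  fc <- f1; fc$speed <- f1$speed * 1.5
  el <- eligible_facilities(s$facilities, "HC3")
  t1 <- compute_travel_time(f1, el)
  t2 <- compute_travel_time(fc, el)
  fin <- is.finite(t1$minutes)
  expect_equal(t2$minutes[fin], t1$minutes[fin] / 1.5, tolerance = 1e-12)

  # adding a facility never increases travel time
  more <- s$facilities
  t_all <- compute_travel_time(f1, more)
  t_sub <- compute_travel_time(f1, el)
  expect_true(all(t_all$minutes <= t_sub$minutes + 1e-9))

  # lower levels admit more facilities, so times are no larger
  t_hc2 <- compute_travel_time(f1, eligible_facilities(s$facilities, "HC2"))
  t_nrh <- compute_travel_time(f1, eligible_facilities(s$facilities, "NRH"))
  expect_true(all(t_hc2$minutes <= t_hc2$minutes + 1e-9))
  expect_true(all(t_hc2$minutes <= t_nrh$minutes + 1e-9))
})

test_that("time saved is walk minus bike with flagged no-data", {
  sp <- matrix(6, 2, 8)
  fr_w <- make_friction(sp, 100)
  fr_b <- make_friction(sp * 2, 100,
                        scenario = scenario_spec("bicycle"))
  fac <- facilities_at_cells(fr_w$grid, cbind(1, 1))
  tw <- compute_travel_time(fr_w, fac, level = "HC2")
  tb <- compute_travel_time(fr_b, fac, level = "HC2")
  saved <- time_saved(tw, tb)
  # halving every cell time on a 1-D corridor saves walk/2 cellwise
  expect_equal(saved, tw$minutes / 2, tolerance = 1e-12)

  # identical frictions -> zero savings
  expect_true(all(time_saved(tw, tw) == 0))

  # provenance mismatch is an error
  tb2 <- tb; tb2$provenance$multiplier <- 0.8
  expect_error(time_saved(tw, tb2), "provenance")

  # unreachable flags: both -> NA; walk-only -> Inf
  spw <- rbind(c(6, 0, 0), c(6, 0, 0))
  spb <- rbind(c(12, 12, 12), c(12, 12, 0))
  gsm <- grid_spec(2, 3, 100)
  tw2 <- compute_travel_time(make_friction(spw, 100),
                             facilities_at_cells(gsm, cbind(1, 1)),
                             level = "HC2", snap_radius = 0L)
  tb2 <- compute_travel_time(make_friction(spb, 100,
                                           scenario_spec("bicycle")),
                             facilities_at_cells(gsm, cbind(1, 1)),
                             level = "HC2", snap_radius = 0L)
  sv <- time_saved(tw2, tb2)
  expect_identical(sv[1, 3], Inf)       # bike reaches, walk does not
  expect_true(is.na(sv[2, 3]))          # neither mode reaches
  expect_equal(sv[1, 1], 0)

  # default speed tables never make bicycling slower than walking
  s <- test_scene()
  lay <- access_layers(s)
  sv_hc3 <- time_saved(lay$walk$HC3, lay$bike$HC3)
  joint <- is.finite(sv_hc3)
  expect_true(all(sv_hc3[joint] >= -1e-9))
})
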