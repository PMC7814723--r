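# direct (non-spatial) fixture for the learners: density drives the
# response, poverty is pure noise
make_model_data <- function(n, seed, slope = 2, noise_sd = 0.5) {
  withr::with_seed(seed, {
    u <- rnorm(6, 0, 2)
    d <- data.frame(
      density = runif(n, 0, 10),
      poverty = runif(n),
      subregion = factor(sample(letters[1:6], n, replace = TRUE)))
    d$walk_HC2 <- slope * d$density + u[as.integer(d$subregion)] +
      rnorm(n, 0, noise_sd)
    d
  })
}

test_that("point sampling hits n, stays in the mask and is reproducible", {
  s <- test_scene()
  lay <- access_layers(s)
  p1 <- suppressMessages(sample_points(s, lay, n = 400, seed = 9))
  p2 <- suppressMessages(sample_points(s, lay, n = 400, seed = 9))
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 400L)
  rc <- point_to_cell(s$grid, p1$x, p1$y)
  expect_true(all(s$study_mask[rc]))
  expect_true(all(is.finite(as.matrix(p1[, -(1:3)]))))
  expect_true(all(paste0("walk_", facility_levels) %in% names(p1)))
  expect_true(all(paste0("saved_", facility_levels) %in% names(p1)))
})

test_that("VIF screening follows the 1/(1-R2) rule", {
  set.seed(31)
  d <- data.frame(a = rnorm(1000), b = rnorm(1000))
  out <- vif_screen(d, c("a", "b"))
  expect_true(all(abs(out$vif - 1) < 0.1))

  # agreement with an independent VIF implementation
  d$c <- 0.8 * d$a + 0.6 * rnorm(1000)
  d$y <- rnorm(1000)
  ours <- vif_screen(d, c("a", "b", "c"))$vif
  ref <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(ours[names(ref)], ref, tolerance = 1e-8)

  # an exact duplicate is removed
  d$a2 <- d$a
  expect_warning(out2 <- vif_screen(d, c("a", "a2", "b")), "collinear")
  expect_length(out2$retained, 2L)
  expect_true("b" %in% out2$retained)
})

test_that("train/test split is exact, disjoint and exhaustive", {
  d <- data.frame(i = 1:5000)
  sp <- split_train_test(d, 0.85, seed = 2)
  expect_equal(nrow(sp$train), 4250L)
  expect_equal(nrow(sp$test), 750L)
  expect_setequal(c(sp$train$i, sp$test$i), d$i)
  expect_error(split_train_test(d, 1), "strictly between")
})

test_that("the power ladder recovers known distribution shapes", {
  withr::with_seed(8, {
    xn <- rnorm(2000, mean = 10)
    xl <- rlnorm(2000, sdlog = 0.8)
  })
  tn <- tukey_transform(xn)
  expect_lt(abs(tn$lambda - 1), 0.25 + 1e-9)
  tl <- tukey_transform(xl)
  expect_lt(abs(tl$lambda - 0), 0.25 + 1e-9)
  expect_equal(mean(tn$transformed), 0, tolerance = 1e-10)
  # the stored transform reproduces itself on the training data
  expect_equal(tn$apply(xn), tn$transformed, tolerance = 1e-12)
  expect_error(tukey_transform(rep(2, 10)), "constant")
})

test_that("forest tuning selects by OOB MAE and reports honest metrics", {
  d <- make_model_data(600, seed = 12)
  sp <- split_train_test(d, 0.85, seed = 1)
  fit <- fit_forest(sp$train, sp$test, "walk_HC2", ntree_grid = 150,
                    seed = 3)
  expect_true(fit$mtry %in% 1:3)
  expect_lte(fit$metrics[["MAE"]], fit$metrics[["RMSE"]])
  expect_gt(fit$metrics[["R2"]], 0.8)
  expect_error(fit_forest(sp$train, sp$test, "walk_HC2",
                          mtry_grid = integer(0)), "empty")
})

test_that("permutation importance ranks drivers over noise", {
  d <- make_model_data(600, seed = 13)
  sp <- split_train_test(d, 0.85, seed = 1)
  fit <- fit_forest(sp$train, sp$test, "walk_HC2", ntree_grid = 150,
                    seed = 3)
  imp <- conditional_importance(fit, n_iter = 5, seed = 4)
  expect_setequal(imp$rank, 1:3)
  expect_equal(imp$predictor[imp$rank == 1], "density")
  # the pure-noise predictor scores near zero and ranks last
  noise_imp <- imp$importance[imp$predictor == "poverty"]
  expect_lt(noise_imp, 0.05 * max(imp$importance))

  # averaging across iterations reduces the spread of the scores
  reps1 <- replicate(6, conditional_importance(fit, n_iter = 1,
                                               seed = sample.int(1e4, 1))
                     $importance[1])
  reps5 <- replicate(6, conditional_importance(fit, n_iter = 5,
                                               seed = sample.int(1e4, 1))
                     $importance[1])
  expect_lt(sd(reps5), sd(reps1) + 1e-9)
})

test_that("partial dependence recovers a linear signal inside the fences", {
  d <- make_model_data(800, seed = 14)
  sp <- split_train_test(d, 0.85, seed = 1)
  fit <- fit_forest(sp$train, sp$test, "walk_HC2", mtry_grid = 3,
                    ntree_grid = 200, seed = 3)
  pd <- partial_dependence(fit, "density", grid_size = 20)
  slope <- coef(lm(yhat ~ value, pd))[2]
  expect_gt(slope, 1.5)
  expect_lt(slope, 2.5)
  # trimmed grid bounds equal the boxplot fences
  xs <- sp$train$density
  q <- quantile(xs, c(0.25, 0.75), names = FALSE)
  lo <- max(min(xs), q[1] - 1.5 * diff(q))
  hi <- min(max(xs), q[2] + 1.5 * diff(q))
  expect_equal(range(pd$value), c(lo, hi), tolerance = 1e-9)
})

test_that("BIC selection recovers a simulated interaction and effect signs", {
  sim <- function(seed, n = 600) {
    withr::with_seed(seed, {
      g <- factor(sample(1:8, n, replace = TRUE))
      u <- rnorm(8, 0, 4)
      pov <- runif(n, 0.05, 0.95)
      dens <- rlnorm(n, 5, 1)
      p_t <- pov - mean(pov)
      d_t <- log(dens) - mean(log(dens))
      y <- 50 + 30 * p_t - 40 * d_t + 25 * p_t * d_t + u[g] + rnorm(n, 0, 5)
      data.frame(poverty = pov, density = dens, subregion = g,
                 walk_HC2 = y)
    })
  }
  wins <- 0L; pov_pos <- 0L
  for (seed in 1:5) {
    d <- sim(seed)
    sp <- split_train_test(d, 0.85, seed = seed)
    mm <- fit_mixed_models(sp$train, sp$test, "walk_HC2")
    expect_equal(mm$candidates$BIC[mm$candidates$name == mm$formula_name],
                 min(mm$candidates$BIC))
    expect_lte(mm$metrics[["MAE"]], mm$metrics[["RMSE"]])
    expect_gte(mm$icc, 0); expect_lte(mm$icc, 1)
    if (mm$formula_name == "poverty_density_interaction") wins <- wins + 1L
    co <- mm$coefficients
    if ("pov_t" %in% rownames(co) &&
        co["pov_t", "estimate"] > 0 && co["pov_t", "p"] < 0.05)
      pov_pos <- pov_pos + 1L
  }
  expect_gte(wins, 3L)      # interaction model wins BIC in a majority
  expect_gte(pov_pos, 4L)   # positive poverty effect recovered
})

test_that("five candidates are enumerated with a null baseline", {
  d <- make_model_data(400, seed = 15)
  sp <- split_train_test(d, 0.85, seed = 1)
  mm <- fit_mixed_models(sp$train, sp$test, "walk_HC2")
  expect_setequal(mm$candidates$name,
                  c("null", "poverty", "density", "poverty_density",
                    "poverty_density_interaction"))
  expect_false(is.na(mm$null_icc))
})

test_that("model comparison subtracts matched metric tables", {
  s <- test_scene()
  lay <- access_layers(s)
  pts <- suppressMessages(sample_points(s, lay, n = 350, seed = 17))
  sp <- split_train_test(pts, seed = 18)
  ff <- fit_forest_suite(sp$train, sp$test, levels = c("HC2", "HC3"),
                         ntree_grid = 100, seed = 19)
  mm <- fit_mixed_suite(sp$train, sp$test, levels = c("HC2", "HC3"))
  cmp <- compare_models(ff, mm)
  expect_equal(nrow(cmp), 4L)    # 2 levels x 2 scenarios
  # deltas are a plain subtraction of the metric tables
  expect_equal(cmp$dMAE[1],
               ff[[1]]$metrics[["MAE"]] - mm[[1]]$metrics[["MAE"]])
  # identical suites give all-zero deltas
  zero <- compare_models(ff, ff)
  expect_true(all(abs(c(zero$dMAE, zero$dRMSE, zero$dR2)) < 1e-12))
  expect_error(compare_models(ff[1:3], mm), "pairs")
  # every fitted model obeys MAE <= RMSE
  for (f in c(ff, mm))
    expect_lte(f$metrics[["MAE"]], f$metrics[["RMSE"]])
})
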