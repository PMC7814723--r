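#' Compute the full stack of access layers for a scene
#'
#' Walking and bicycling travel-time surfaces for every facility tier at one
#' speed multiplier — the twelve access layers the covariate models draw
#' from (bike-saved layers are derived at sampling time as walk - bike).
#'
#' @param scene A `synthetic_scene`.
#' @param multiplier Speed multiplier (default 1).
#' @return List with elements `walk` and `bike`, each a named list of
#'   `travel_time_surface` objects per tier level.
#' @export
access_layers <- function(scene, multiplier = 1) {
  road_raster <- rasterize_roads(scene$roads, scene$grid)
  one_mode <- function(mode) {
    fr <- scene_friction(scene, scenario_spec(mode, multiplier), road_raster)
    out <- lapply(facility_levels, function(lv)
      compute_travel_time(fr, eligible_facilities(scene$facilities, lv),
                          level = lv))
    names(out) <- facility_levels
    out
  }
  list(walk = one_mode("walk"), bike = one_mode("bicycle"))
}

#' Response column name for a scenario and tier level
#'
#' @param scenario `"walk"` (minutes walking) or `"saved"` (minutes saved
#'   by bicycling).
#' @param level Tier level in [facility_levels].
#' @return Column name such as `"walk_HC3"`.
#' @export
response_col <- function(scenario, level) {
  stopifnot(scenario %in% c("walk", "saved"))
  paste0(scenario, "_", level)
}

#' Sample random points and extract the model covariates
#'
#' Draws `n` uniform random points inside the study mask and reads, at each
#' point, population density (persons/km2), poverty, walking minutes to all
#' six tier levels and bicycling minutes-saved to all six levels, plus the
#' subregion id. Points falling on cells where any layer is missing or
#' infinite are resampled (count reported via a message).
#'
#' @param scene A `synthetic_scene`.
#' @param layers Output of [access_layers()].
#' @param n Number of points (default 5000).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Data frame with `x`, `y`, `subregion` (factor), `density`,
#'   `poverty`, `walk_<level>` and `saved_<level>` columns.
#' @export
sample_points <- function(scene, layers, n = 5000, seed = 1L) {
  grid <- scene$grid
  cs <- grid$cell_size
  ext_x <- grid$origin[1] + c(0, grid$ncols) * cs
  ext_y <- grid$origin[2] + c(0, grid$nrows) * cs
  dens <- scene$population / (cs / 1000)^2
  saved <- lapply(facility_levels, function(lv)
    time_saved(layers$walk[[lv]], layers$bike[[lv]]))
  names(saved) <- facility_levels

  withr::with_seed(seed, {
    rows <- vector("list", 0L)
    got <- 0L; dropped <- 0L; guard <- 0L
    while (got < n && guard < 60L) {
      guard <- guard + 1L
      m <- max(n - got, 32L)
      x <- stats::runif(m, ext_x[1], ext_x[2])
      y <- stats::runif(m, ext_y[1], ext_y[2])
      rc <- point_to_cell(grid, x, y)
      keep <- !is.na(rc[, 1L]) & scene$study_mask[rc]
      vals <- data.frame(x = x[keep], y = y[keep])
      rc <- rc[keep, , drop = FALSE]
      vals$subregion <- scene$subregions[rc]
      vals$density <- dens[rc]
      vals$poverty <- scene$poverty[rc]
      for (lv in facility_levels) {
        vals[[response_col("walk", lv)]] <- layers$walk[[lv]]$minutes[rc]
        vals[[response_col("saved", lv)]] <- saved[[lv]][rc]
      }
      ok <- stats::complete.cases(vals) &
        apply(vals[, -(1:3), drop = FALSE], 1L, function(r) all(is.finite(r)))
      dropped <- dropped + sum(!ok)
      vals <- vals[ok, , drop = FALSE]
      if (nrow(vals)) {
        rows[[length(rows) + 1L]] <- utils::head(vals, n - got)
        got <- got + nrow(utils::head(vals, n - got))
      }
    }
    if (got < n) stop("could not place the requested number of points")
    if (dropped > 0)
      message(sprintf("resampled %d points on missing/unreachable cells",
                      dropped))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$subregion <- factor(out$subregion)
    out
  })
}

#' Variance-inflation-factor screen
#'
#' Computes VIF_j = 1/(1 - R2_j) from regressing each predictor on the
#' others and iteratively removes the worst offender until all VIFs are at
#' or below the threshold (default 10, the conventional multicollinearity
#' cutoff).
#'
#' @param table Data frame holding the predictors.
#' @param predictors Character vector of (numeric) predictor columns.
#' @param threshold VIF cutoff (default 10).
#' @return List with `retained` (names) and `vif` (named vector of final
#'   VIF values).
#' @export
vif_screen <- function(table, predictors, threshold = 10) {
  stopifnot(length(predictors) >= 2L, nrow(table) > length(predictors))
  current <- predictors
  repeat {
    if (length(current) < 2L) break
    vifs <- vapply(current, function(p) {
      fml <- stats::reformulate(setdiff(current, p), response = p)
      r2 <- suppressWarnings(summary(stats::lm(fml, data = table))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    if (all(vifs <= threshold)) break
    worst <- names(which.max(vifs))
    warning("removing collinear predictor: ", worst,
            sprintf(" (VIF %.3g)", vifs[worst]))
    current <- setdiff(current, worst)
  }
  if (length(current) >= 2L) {
    vifs <- vapply(current, function(p) {
      fml <- stats::reformulate(setdiff(current, p), response = p)
      1 / (1 - summary(stats::lm(fml, data = table))$r.squared)
    }, numeric(1))
  } else vifs <- stats::setNames(rep(NA_real_, length(current)), current)
  list(retained = current, vif = vifs)
}

#' Deterministic train/test split
#'
#' @param table Data frame of samples.
#' @param train_frac Training fraction in (0, 1); default 0.85 (4250/750 at
#'   n = 5000).
#' @param seed Integer seed.
#' @return List with disjoint, exhaustive `train` and `test` data frames.
#' @export
split_train_test <- function(table, train_frac = 0.85, seed = 1L) {
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must lie strictly between 0 and 1")
  n <- nrow(table)
  n_train <- round(n * train_frac)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

eval_metrics <- function(obs, pred) {
  res <- obs - pred
  c(MAE = mean(abs(res)),
    RMSE = sqrt(mean(res^2)),
    R2 = 1 - sum(res^2) / sum((obs - mean(obs))^2))
}

#' Fit and tune a random forest access model
#'
#' Fits one forest per (mtry, ntree) combination with predictors population
#' density, poverty and subregion, selects the combination with the lowest
#' out-of-bag MAE, and evaluates the winner on the held-out test set
#' (predictive R2 = 1 - SS_res/SS_tot, which may be negative).
#'
#' @param train,test Data frames from [split_train_test()].
#' @param response Response column name (see [response_col()]).
#' @param mtry_grid Candidate mtry values (default 1:3).
#' @param ntree_grid Candidate tree counts (default 500).
#' @param seed Integer seed for the forest fits.
#' @return A `model_fit` list: `kind = "forest"`, the tuned `model` (ranger,
#'   with in-bag counts kept for importance), `mtry`, `ntree`, `oob_mae`,
#'   `metrics` (MAE/RMSE/R2 on test), and the training data for later
#'   importance/partial-dependence calls.
#' @export
fit_forest <- function(train, test, response, mtry_grid = 1:3,
                       ntree_grid = 500, seed = 1L) {
  if (!length(mtry_grid) || !length(ntree_grid))
    stop("empty hyperparameter grid")
  preds <- c("density", "poverty", "subregion")
  fml <- stats::reformulate(preds, response = response)
  best <- NULL
  for (ntree in ntree_grid) for (mtry in mtry_grid) {
    fit <- ranger::ranger(fml, data = train, num.trees = ntree,
                          mtry = mtry, keep.inbag = TRUE, seed = seed,
                          respect.unordered.factors = "partition",
                          num.threads = 1)
    oob_mae <- mean(abs(train[[response]] - fit$predictions), na.rm = TRUE)
    if (is.null(best) || oob_mae < best$oob_mae)
      best <- list(model = fit, mtry = mtry, ntree = ntree,
                   oob_mae = oob_mae)
  }
  pred <- stats::predict(best$model, data = test, num.threads = 1)$predictions
  structure(c(best,
              list(kind = "forest", response = response,
                   predictors = preds,
                   metrics = eval_metrics(test[[response]], pred),
                   train_data = train)),
            class = "model_fit")
}

# OOB predictions from per-tree predictions and in-bag counts.
oob_mse <- function(model, data, y) {
  all_pred <- stats::predict(model, data = data, predict.all = TRUE,
                             num.threads = 1)$predictions
  inbag <- simplify2array(model$inbag.counts)
  oob <- inbag == 0
  num <- rowSums(all_pred * oob)
  cnt <- rowSums(oob)
  keep <- cnt > 0
  mean((y[keep] - num[keep] / cnt[keep])^2)
}

#' Permutation variable importance averaged over iterations
#'
#' Mean decrease in accuracy measured as the increase in out-of-bag MSE when
#' a predictor's column is permuted, averaged over `n_iter` independent
#' permutations per predictor. Averaging stabilizes the scores.
#'
#' @param fit A `model_fit` from [fit_forest()].
#' @param n_iter Number of permutation iterations (default 20).
#' @param seed Integer seed.
#' @return Data frame with `predictor`, `importance` (mean OOB MSE
#'   increase) and `rank` (1 = most important).
#' @export
conditional_importance <- function(fit, n_iter = 20, seed = 1L) {
  stopifnot(fit$kind == "forest")
  data <- fit$train_data
  y <- data[[fit$response]]
  base <- oob_mse(fit$model, data, y)
  scores <- withr::with_seed(seed, {
    vapply(fit$predictors, function(p) {
      mean(vapply(seq_len(n_iter), function(it) {
        d2 <- data
        d2[[p]] <- d2[[p]][sample.int(nrow(d2))]
        oob_mse(fit$model, d2, y) - base
      }, numeric(1)))
    }, numeric(1))
  })
  data.frame(predictor = fit$predictors, importance = scores,
             rank = rank(-scores, ties.method = "first"),
             row.names = NULL)
}

boxplot_fences <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  c(max(min(x), q[1] - 1.5 * iqr), min(max(x), q[2] + 1.5 * iqr))
}

#' Partial dependence of a forest on one predictor
#'
#' Average model prediction over a grid of the target variable with the
#' remaining predictors marginalized over (a subsample of) the training
#' rows. The grid is restricted to the boxplot fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the training values, trimming
#' outliers.
#'
#' @param fit A `model_fit` from [fit_forest()].
#' @param variable Predictor name (continuous).
#' @param grid_size Number of grid points (default 25).
#' @param trim Apply the boxplot trim (default TRUE).
#' @param n_marginal Max training rows used for marginalization.
#' @param seed Seed for the marginalization subsample.
#' @return Data frame with `value` and `yhat`.
#' @export
partial_dependence <- function(fit, variable, grid_size = 25, trim = TRUE,
                               n_marginal = 500, seed = 1L) {
  stopifnot(fit$kind == "forest", variable %in% fit$predictors)
  xs <- fit$train_data[[variable]]
  rng <- if (trim) boxplot_fences(xs) else range(xs)
  grid_vals <- seq(rng[1], rng[2], length.out = grid_size)
  d <- fit$train_data
  if (nrow(d) > n_marginal)
    d <- d[withr::with_seed(seed, sample.int(nrow(d), n_marginal)), ]
  yhat <- vapply(grid_vals, function(v) {
    d[[variable]] <- v
    mean(stats::predict(fit$model, data = d,
                        num.threads = 1)$predictions)
  }, numeric(1))
  data.frame(value = grid_vals, yhat = yhat)
}

#' Tukey ladder-of-powers transformation toward normality
#'
#' Picks the power lambda on a grid (default -2..2 in steps of 0.025) that
#' maximizes the Shapiro-Wilk W of the transformed values (computed on an
#' evenly spaced order-statistic subsample capped at 5000 observations).
#' The transform is `x^lambda` for positive lambda, `log(x)` at 0 and
#' `-x^lambda` for negative lambda; non-positive inputs are first shifted
#' up (reported via a message). The output is centered to mean zero.
#'
#' @param x Numeric vector, not constant.
#' @param lambdas Candidate powers.
#' @return List with `lambda`, `transformed` (centered), `shift`, `center`,
#'   and `apply`, a function applying the same transform to new data.
#' @export
tukey_transform <- function(x, lambdas = seq(-2, 2, by = 0.025)) {
  if (stats::sd(x) == 0) stop("cannot transform a constant vector")
  shift <- 0
  if (min(x) <= 0) {
    shift <- -min(x) + 1e-6 * max(diff(range(x)), 1)
    message(sprintf("applying positive shift %.6g before power transform",
                    shift))
  }
  xp <- x + shift
  sub <- if (length(xp) > 5000) {
    sort(xp)[round(seq(1, length(xp), length.out = 5000))]
  } else xp
  tf <- function(v, l) {
    if (l > 0) v^l else if (l == 0) log(v) else -(v^l)
  }
  w <- vapply(lambdas, function(l) {
    tv <- tf(sub, l)
    if (!all(is.finite(tv)) || stats::sd(tv) == 0) return(-Inf)
    tryCatch(stats::shapiro.test(tv)$statistic, error = function(e) -Inf)
  }, numeric(1))
  lambda <- lambdas[which.max(w)]
  tx <- tf(xp, lambda)
  center <- mean(tx)
  list(lambda = lambda, transformed = tx - center, shift = shift,
       center = center,
       apply = function(v) tf(v + shift, lambda) - center)
}

#' Fit the candidate linear mixed-effects models and select by BIC
#'
#' Transforms poverty and population density with [tukey_transform()],
#' centers them, forms their interaction, and fits the five candidate fixed
#' effect sets — null, poverty, density, poverty + density, and
#' poverty + density + interaction — each with a subregion random intercept
#' (maximum likelihood, so BICs are comparable). The null model is fit
#' first to confirm the grouping variable matters (its ICC is reported).
#' The lowest-BIC candidate is evaluated on the test set.
#'
#' @param train,test Data frames from [split_train_test()].
#' @param response Response column name.
#' @return A `model_fit` list: `kind = "mixed"`, the winning `model`
#'   (lmerTest), `formula_name`, `candidates` (name, BIC, singular flag),
#'   `coefficients` (estimate, SE, CI, t, p), variance components `sigma2`,
#'   `tau00`, `icc`, `null_icc`, and test `metrics`.
#' @export
fit_mixed_models <- function(train, test, response) {
  tp <- suppressMessages(tukey_transform(train$poverty))
  td <- suppressMessages(tukey_transform(train$density))
  tr <- train
  tr$pov_t <- tp$transformed
  tr$dens_t <- td$transformed
  tr$inter <- tr$pov_t * tr$dens_t
  te <- test
  te$pov_t <- tp$apply(test$poverty)
  te$dens_t <- td$apply(test$density)
  te$inter <- te$pov_t * te$dens_t

  cand_rhs <- list(
    null = "1",
    poverty = "pov_t",
    density = "dens_t",
    poverty_density = "pov_t + dens_t",
    poverty_density_interaction = "pov_t + dens_t + inter")
  fits <- list(); bics <- numeric(0); singular <- logical(0)
  for (nm in names(cand_rhs)) {
    fml <- stats::as.formula(
      paste(response, "~", cand_rhs[[nm]], "+ (1 | subregion)"))
    fit <- tryCatch(
      lmerTest::lmer(fml, data = tr, REML = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) { warning("candidate failed to fit: ", nm); next }
    sing <- lme4::isSingular(fit)
    if (sing && nm != "null") {
      warning("singular fit, candidate dropped: ", nm)
      next
    }
    fits[[nm]] <- fit
    bics <- c(bics, stats::setNames(stats::BIC(fit), nm))
    singular <- c(singular, stats::setNames(sing, nm))
  }
  if (!length(fits)) stop("no candidate mixed model could be fit")

  vc_of <- function(fit) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau00 <- vc$vcov[vc$grp == "subregion"]
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    c(sigma2 = sigma2, tau00 = tau00, icc = tau00 / (tau00 + sigma2))
  }
  null_icc <- if ("null" %in% names(fits)) vc_of(fits$null)[["icc"]]
              else NA_real_

  best_name <- names(which.min(bics))
  best <- fits[[best_name]]
  co <- as.data.frame(summary(best)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")[seq_len(ncol(co))]
  co$ci_lo <- co$estimate - 1.96 * co$se
  co$ci_hi <- co$estimate + 1.96 * co$se
  pred <- stats::predict(best, newdata = te, allow.new.levels = TRUE)
  vc <- vc_of(best)

  structure(list(kind = "mixed", response = response, model = best,
                 formula_name = best_name, models = fits,
                 candidates = data.frame(name = names(bics), BIC = bics,
                                         singular = singular,
                                         row.names = NULL),
                 coefficients = co,
                 sigma2 = vc[["sigma2"]], tau00 = vc[["tau00"]],
                 icc = vc[["icc"]], null_icc = null_icc,
                 transforms = list(poverty = tp, density = td),
                 metrics = eval_metrics(te[[response]], pred)),
            class = "model_fit")
}

#' Fit the forest and mixed-model suites over all responses
#'
#' Twelve responses: walking minutes and bicycling minutes-saved for each of
#' the six tier levels. `fit_forest_suite()` tunes one forest per response;
#' `fit_mixed_suite()` runs the BIC-selected mixed-model workflow per
#' response (five candidates each).
#'
#' @param train,test Data frames from [split_train_test()].
#' @param levels Tier levels (default all six).
#' @param scenarios `"walk"`, `"saved"` or both (default).
#' @param ... Passed on to [fit_forest()].
#' @return Named list of `model_fit` objects, keyed `<scenario>_<level>`.
#' @export
fit_forest_suite <- function(train, test, levels = facility_levels,
                             scenarios = c("walk", "saved"), ...) {
  fits <- list()
  for (sc in scenarios) for (lv in levels) {
    resp <- response_col(sc, lv)
    fits[[resp]] <- fit_forest(train, test, resp, ...)
    fits[[resp]]$level <- lv
    fits[[resp]]$scenario <- sc
  }
  fits
}

#' @rdname fit_forest_suite
#' @export
fit_mixed_suite <- function(train, test, levels = facility_levels,
                            scenarios = c("walk", "saved")) {
  fits <- list()
  for (sc in scenarios) for (lv in levels) {
    resp <- response_col(sc, lv)
    fits[[resp]] <- fit_mixed_models(train, test, resp)
    fits[[resp]]$level <- lv
    fits[[resp]]$scenario <- sc
  }
  fits
}

metrics_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(level = f$level, scenario = f$scenario,
               MAE = f$metrics[["MAE"]], RMSE = f$metrics[["RMSE"]],
               R2 = f$metrics[["R2"]], row.names = NULL)))
}

#' Head-to-head accuracy comparison of forest and mixed models
#'
#' Per matched (level, scenario) pair, the difference in test-set MAE, RMSE
#' and R2 with the forest as reference: `delta = forest - mixed`, so a
#' negative MAE/RMSE delta and a positive R2 delta mean the forest wins.
#'
#' @param forest_fits,mixed_fits Suites from [fit_forest_suite()] /
#'   [fit_mixed_suite()] evaluated on the same test set.
#' @return Data frame with one row per pair and `dMAE`, `dRMSE`, `dR2`.
#' @export
compare_models <- function(forest_fits, mixed_fits) {
  ft <- metrics_table(forest_fits)
  mt <- metrics_table(mixed_fits)
  key <- function(t) paste(t$level, t$scenario)
  if (!setequal(key(ft), key(mt)) || nrow(ft) != nrow(mt))
    stop("forest and mixed suites do not cover the same (level, scenario) pairs")
  mt <- mt[match(key(ft), key(mt)), ]
  data.frame(level = ft$level, scenario = ft$scenario,
             dMAE = ft$MAE - mt$MAE,
             dRMSE = ft$RMSE - mt$RMSE,
             dR2 = ft$R2 - mt$R2, row.names = NULL)
}
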