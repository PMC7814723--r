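#' Parameters for the synthetic landscape generator
#'
#' Defaults describe a small country-like landscape: population concentrated
#' in a handful of log-normal urban clusters, poverty highest away from the
#' clusters (rural-skewed, negatively correlated with log density), facility
#' counts falling steeply with tier and placement biased toward dense areas
#' (more strongly so for higher tiers), a road network connecting cluster
#' centers (primary), towns (secondary) and local fill (tertiary), and
#' protected-area barriers covering a small fraction of the landscape.
#'
#' @param n_clusters Number of population clusters.
#' @param total_population Total persons summed over the landscape.
#' @param facility_counts Named integer vector of per-tier facility counts,
#'   non-increasing with tier; every tier must have at least one facility.
#' @param poverty_density_cor Target Pearson correlation between poverty and
#'   `log(1 + population density)`; must be negative for the rural-poor
#'   structure the analysis assumes.
#' @param poverty_noise Standard-deviation of the smooth poverty noise field
#'   relative to the density signal (on the logit scale).
#' @param facility_wealth_bias Exponent on `(1 - poverty)` in the facility
#'   siting weights. Positive values encode the urban/wealth bias of
#'   facility placement — poorer areas get fewer nearby facilities even at
#'   equal catchment population — which is the poverty-access coupling the
#'   equity models are meant to detect. 0 disables it.
#' @param road_density Multiplier on the number of tertiary fill roads.
#' @param barrier_fraction Fraction of landscape area covered by
#'   protected-area rectangles, in [0, 1).
#' @param n_parishes,n_subregions Zone counts for the two nested admin
#'   levels.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_clusters = 12,
                         total_population = 1e6,
                         facility_counts = c(HC2 = 40, HC3 = 20, HC4 = 8,
                                             GH = 4, RRH = 2, NRH = 1),
                         poverty_density_cor = -0.5,
                         poverty_noise = 1,
                         facility_wealth_bias = 2,
                         road_density = 1,
                         barrier_fraction = 0.05,
                         n_parishes = 150,
                         n_subregions = 8) {
  if (any(facility_counts <= 0))
    stop("every facility tier needs a count of at least one")
  if (!identical(names(facility_counts), facility_levels))
    names(facility_counts) <- facility_levels
  if (any(diff(facility_counts) > 0))
    warning("facility counts usually decrease with tier")
  if (barrier_fraction >= 1) stop("barrier_fraction must be < 1")
  if (poverty_density_cor >= 0)
    stop("poverty_density_cor must be negative")
  structure(list(n_clusters = n_clusters,
                 total_population = total_population,
                 facility_counts = facility_counts,
                 poverty_density_cor = poverty_density_cor,
                 poverty_noise = poverty_noise,
                 facility_wealth_bias = facility_wealth_bias,
                 road_density = road_density,
                 barrier_fraction = barrier_fraction,
                 n_parishes = n_parishes,
                 n_subregions = n_subregions),
            class = "scene_params")
}

#' Read scene parameters from a YAML block
#'
#' @param path YAML file whose top-level keys match [scene_params()]
#'   arguments.
#' @return A `scene_params` list.
#' @export
scene_params_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$facility_counts))
    vals$facility_counts <- unlist(vals$facility_counts)
  do.call(scene_params, vals)
}

# Separable Gaussian blur with edge renormalization.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  conv1 <- function(mat, kern) {
    nr <- nrow(mat); nc <- ncol(mat); rr <- (length(kern) - 1L) %/% 2L
    out <- matrix(0, nr, nc); wsum <- matrix(0, nr, nc)
    for (off in -rr:rr) {
      w <- kern[off + rr + 1L]
      src <- pmin(pmax(seq_len(nr) + off, 1L), nr)
      # clamp-at-edge would bias; instead accumulate only valid rows
      valid <- (seq_len(nr) + off) >= 1L & (seq_len(nr) + off) <= nr
      out[valid, ] <- out[valid, ] + w * mat[seq_len(nr)[valid] + off, ]
      wsum[valid, ] <- wsum[valid, ] + w
    }
    out / wsum
  }
  t(conv1(t(conv1(m, k)), k))
}

# Minimum spanning tree over points (Prim), returns edge index pairs.
mst_edges <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  d <- as.matrix(stats::dist(cbind(x, y)))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  edges <- matrix(0L, n - 1L, 2L)
  for (e in seq_len(n - 1L)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    k <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    from <- which(in_tree)[k[1L]]; to <- which(!in_tree)[k[2L]]
    edges[e, ] <- c(from, to)
    in_tree[to] <- TRUE
  }
  edges
}

# Sample `n` distinct cells with probability proportional to `weights`.
sample_cells <- function(weights, n) {
  idx <- sample.int(length(weights), n, replace = FALSE, prob = weights)
  cbind(row = (idx - 1L) %% nrow(weights) + 1L,
        col = (idx - 1L) %/% nrow(weights) + 1L)
}

#' Generate administrative zones as a Voronoi tessellation
#'
#' Places `k` seed points uniformly in the masked area and assigns each cell
#' to its nearest seed, producing `k` non-overlapping zones that tile the
#' study area. On a connected mask the resulting queen-contiguity graph is
#' connected.
#'
#' @param seed Integer RNG seed.
#' @param grid A [grid_spec()].
#' @param k Number of zones (>= 4 and at most the number of masked cells).
#' @param mask Optional logical matrix; cells outside get zone `NA`.
#' @return List with `zones` (integer matrix of zone ids 1..k) and `seeds`
#'   (the seed cells).
#' @export
generate_parishes <- function(seed, grid, k, mask = NULL) {
  stopifnot_grid(grid)
  if (k < 4L) stop("k must be at least 4")
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrows, grid$ncols)
  n_cells <- sum(mask)
  if (k > n_cells) stop("k exceeds the number of cells in the mask")
  withr::with_seed(seed, {
    idx <- sample(which(mask), k)
    sr <- (idx - 1L) %% grid$nrows + 1L
    sc <- (idx - 1L) %/% grid$nrows + 1L
    cc <- cell_centers(grid)
    sx <- cc$x[cbind(sr, sc)]; sy <- cc$y[cbind(sr, sc)]
    zones <- matrix(NA_integer_, grid$nrows, grid$ncols)
    px <- cc$x[mask]; py <- cc$y[mask]
    # nearest seed per cell, chunked to bound memory
    nearest <- integer(length(px))
    chunk <- 200000L %/% max(1L, k)
    starts <- seq(1L, length(px), by = max(1L, chunk))
    for (s in starts) {
      e <- min(s + chunk - 1L, length(px))
      d2 <- outer(px[s:e], sx, "-")^2 + outer(py[s:e], sy, "-")^2
      nearest[s:e] <- max.col(-d2, ties.method = "first")
    }
    zones[mask] <- nearest
    list(zones = zones, seeds = cbind(row = sr, col = sc))
  })
}

#' Generate a complete synthetic scene
#'
#' Builds every input layer the accessibility pipeline needs, with the
#' statistical structure the analysis assumes: clustered log-normal
#' population, a smooth poverty field calibrated to a target negative
#' correlation with log population density, facility placement biased toward
#' dense cells (increasingly so for higher tiers), roads connecting cluster
#' centers (primary), towns (secondary) and local fill (tertiary),
#' rectangular protected-area barriers, a landcover mosaic over the model's
#' classes, and two nested levels of Voronoi admin zones. Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param seed Integer RNG seed.
#' @param grid A [grid_spec()].
#' @param params A [scene_params()] list.
#' @return A `synthetic_scene` list with elements `grid`, `landcover`,
#'   `roads`, `barriers`, `population`, `poverty`, `facilities`, `parishes`,
#'   `subregions`, `parish_subregion`, `study_mask`, `params`, `seed`.
#' @export
generate_scene <- function(seed, grid, params = scene_params()) {
  stopifnot_grid(grid)
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  nr <- grid$nrows; nc <- grid$ncols
  cc <- cell_centers(grid)
  extent <- c(nc, nr) * grid$cell_size
  mask <- matrix(TRUE, nr, nc)

  scene <- withr::with_seed(seed, {
    ## population: mixture of Gaussian clusters with log-normal noise
    k <- params$n_clusters
    cxr <- grid$origin[1] + stats::runif(k, 0.08, 0.92) * extent[1]
    cyr <- grid$origin[2] + stats::runif(k, 0.08, 0.92) * extent[2]
    sig <- stats::runif(k, 0.04, 0.12) * min(extent)
    w <- stats::rlnorm(k, meanlog = 0, sdlog = 0.8)
    intensity <- matrix(1e-3, nr, nc)
    for (i in seq_len(k)) {
      d2 <- (cc$x - cxr[i])^2 + (cc$y - cyr[i])^2
      intensity <- intensity + w[i] * exp(-d2 / (2 * sig[i]^2))
    }
    noise <- exp(matrix(stats::rnorm(nr * nc, 0, 0.6), nr, nc))
    pop <- intensity * noise
    pop <- pop / sum(pop[mask]) * params$total_population
    dens_km2 <- pop / (grid$cell_size / 1000)^2
    log_dens <- log1p(dens_km2)

    ## poverty: logistic(a - b * smoothed log-density + smooth noise),
    ## b calibrated to the target correlation with log(1 + density)
    sm <- 0.03 * min(nr, nc)
    z <- gaussian_blur(log_dens, sm)
    z <- (z - mean(z)) / stats::sd(z)
    pn <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), sm)
    pn <- (pn - mean(pn)) / stats::sd(pn) * params$poverty_noise
    pov_of_b <- function(b) stats::plogis(-b * z + pn)
    f <- function(b) stats::cor(as.vector(pov_of_b(b)[mask]),
                                as.vector(log_dens[mask])) -
      params$poverty_density_cor
    b_hat <- tryCatch(stats::uniroot(f, c(0, 50))$root,
                      error = function(e) 2)
    poverty <- pov_of_b(b_hat)
    poverty <- pmin(pmax(poverty, 0), 1)

    ## landcover mosaic: vegetation classes from a smooth field, water and
    ## flooded margins from a second field, built-up over the densest cells
    veg <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc),
                         0.04 * min(nr, nc))
    qs <- stats::quantile(veg, c(0.35, 0.65, 0.77, 0.89, 0.95))
    lc <- matrix(landcover_classes$code[match("cropland",
                                              landcover_classes$name)],
                 nr, nc)
    code <- function(nm) landcover_classes$code[landcover_classes$name == nm]
    lc[veg > qs[1]] <- code("grassland")
    lc[veg > qs[2]] <- code("shrublands")
    lc[veg > qs[3]] <- code("forests")
    lc[veg > qs[4]] <- code("sparse_vegetation")
    lc[veg > qs[5]] <- code("bare_areas")
    wat <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc),
                         0.05 * min(nr, nc))
    water <- wat > stats::quantile(wat, 0.98)
    flooded <- gaussian_blur(water * 1, 1.2) > 0.05 & !water
    lc[flooded] <- code("flooded")
    lc[water] <- code("open_water")
    lc[dens_km2 > stats::quantile(dens_km2, 0.985)] <- code("built_up")

    ## barriers: rectangles in sparsely populated country, up to the target
    ## area fraction
    barriers <- data.frame(xmin = numeric(0), ymin = numeric(0),
                           xmax = numeric(0), ymax = numeric(0))
    if (params$barrier_fraction > 0) {
      total_area <- prod(extent)
      placed <- 0
      inv_w <- 1 / (dens_km2 + stats::quantile(dens_km2, 0.25))
      tries <- 0L
      while (placed < params$barrier_fraction * total_area && tries < 100L) {
        tries <- tries + 1L
        ctr <- sample_cells(inv_w * mask, 1L)
        wx <- stats::runif(1, 0.05, 0.15) * extent[1]
        wy <- stats::runif(1, 0.05, 0.15) * extent[2]
        rect <- data.frame(xmin = cc$x[ctr] - wx / 2, ymin = cc$y[ctr] - wy / 2,
                           xmax = cc$x[ctr] + wx / 2, ymax = cc$y[ctr] + wy / 2)
        barriers <- rbind(barriers, rect)
        placed <- placed + wx * wy
      }
    }

    ## cells unsuitable for facility siting: open water, regularly
    ## flooded margins, and protected-area interiors
    excluded <- lc == code("open_water") | lc == code("flooded") |
      rasterize_barriers(barriers, grid)

    ## facilities: siting follows catchment (smoothed) population rather
    ## than single-cell counts, steeper for higher tiers. Using the same
    ## regional field that drives poverty gives the rural-poor access
    ## structure: poor areas are far from facilities even at equal local
    ## density.
    gammas <- c(0.6, 0.9, 1.3, 1.8, 2.4, 3.2)
    catch <- expm1(gaussian_blur(log_dens, sm))
    fac <- do.call(rbind, lapply(seq_along(facility_levels), function(t) {
      wts <- (catch + stats::quantile(catch, 0.5))^gammas[t] *
        (1 - poverty + 0.05)^params$facility_wealth_bias
      wts[excluded] <- 0
      wts[!mask] <- 0
      cells <- sample_cells(wts, params$facility_counts[t])
      jit <- matrix(stats::runif(2 * nrow(cells), -0.3, 0.3), ncol = 2)
      data.frame(
        x = cc$x[cells] + jit[, 1] * grid$cell_size,
        y = cc$y[cells] + jit[, 2] * grid$cell_size,
        level = facility_levels[t])
    }))
    facilities <- facility_set(fac$x, fac$y, fac$level)

    ## roads: primary = MST over cluster centers; secondary = towns to the
    ## nearest cluster center; tertiary = local fill toward the network
    me <- mst_edges(cxr, cyr)
    roads <- data.frame(x0 = cxr[me[, 1]], y0 = cyr[me[, 1]],
                        x1 = cxr[me[, 2]], y1 = cyr[me[, 2]],
                        class = "primary")
    n_towns <- 2L * k
    town_cells <- sample_cells(pmax(dens_km2, 0) * mask, n_towns)
    tx <- cc$x[town_cells]; ty <- cc$y[town_cells]
    near_cl <- max.col(-(outer(tx, cxr, "-")^2 + outer(ty, cyr, "-")^2),
                       ties.method = "first")
    roads <- rbind(roads, data.frame(x0 = tx, y0 = ty,
                                     x1 = cxr[near_cl], y1 = cyr[near_cl],
                                     class = "secondary"))
    n_tert <- max(4L, round(params$road_density * 4L * k))
    vx <- c(cxr, tx); vy <- c(cyr, ty)
    tert_cells <- sample_cells(pmax(dens_km2, 0) * mask, n_tert)
    ox <- cc$x[tert_cells]; oy <- cc$y[tert_cells]
    near_v <- max.col(-(outer(ox, vx, "-")^2 + outer(oy, vy, "-")^2),
                      ties.method = "first")
    roads <- rbind(roads, data.frame(x0 = ox, y0 = oy,
                                     x1 = vx[near_v], y1 = vy[near_v],
                                     class = "tertiary"))

    ## nested admin zones
    par <- generate_parishes(seed + 1L, grid, params$n_parishes, mask)
    sub_idx <- sample(which(mask), params$n_subregions)
    sbr <- (sub_idx - 1L) %% nr + 1L; sbc <- (sub_idx - 1L) %/% nr + 1L
    sxx <- cc$x[cbind(sbr, sbc)]; syy <- cc$y[cbind(sbr, sbc)]
    pax <- cc$x[par$seeds]; pay <- cc$y[par$seeds]
    parish_sub <- max.col(-(outer(pax, sxx, "-")^2 + outer(pay, syy, "-")^2),
                          ties.method = "first")
    subzones <- matrix(parish_sub[par$zones], nr, nc)

    list(grid = grid, landcover = lc, roads = roads, barriers = barriers,
         population = pop, poverty = poverty, facilities = facilities,
         parishes = par$zones, subregions = subzones,
         parish_subregion = parish_sub, study_mask = mask,
         params = params, seed = seed)
  })
  class(scene) <- "synthetic_scene"
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %dx%d cells (%g m); pop %.3g; %d facilities; %d parishes in %d subregions\n",
    x$grid$nrows, x$grid$ncols, x$grid$cell_size, sum(x$population),
    nrow(x$facilities), max(x$parishes, na.rm = TRUE),
    max(x$subregions, na.rm = TRUE)))
  invisible(x)
}

#' Write a scene's layers to plain-text GIS files
#'
#' Rasters go to ESRI ASCII grids, facilities to GeoJSON points, roads and
#' barriers to CSV tables.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- scene$grid
  write_ascii_grid(scene$population, g, file.path(dir, "population.asc"))
  write_ascii_grid(scene$poverty, g, file.path(dir, "poverty.asc"))
  write_ascii_grid(scene$landcover, g, file.path(dir, "landcover.asc"))
  write_ascii_grid(scene$parishes, g, file.path(dir, "parishes.asc"))
  write_ascii_grid(scene$subregions, g, file.path(dir, "subregions.asc"))
  write_points_geojson(scene$facilities, file.path(dir, "facilities.geojson"))
  utils::write.csv(scene$roads, file.path(dir, "roads.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$barriers, file.path(dir, "barriers.csv"),
                   row.names = FALSE)
  invisible(dir)
}
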