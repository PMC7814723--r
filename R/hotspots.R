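# Order-1 queen adjacency between zones of a label raster: two zones are
# neighbors when any of their cells touch, edge or corner.
zone_adjacency <- function(zones) {
  nr <- nrow(zones); nc <- ncol(zones)
  n <- max(zones, na.rm = TRUE)
  pair <- function(a, b) {
    ok <- !is.na(a) & !is.na(b) & a != b
    cbind(a[ok], b[ok])
  }
  pr <- rbind(
    pair(zones[, -nc], zones[, -1L]),          # east
    pair(zones[-nr, ], zones[-1L, ]),          # south
    pair(zones[-nr, -nc], zones[-1L, -1L]),    # south-east
    pair(zones[-nr, -1L], zones[-1L, -nc]))    # south-west
  pr <- unique(rbind(pr, pr[, 2:1, drop = FALSE]))
  nbs <- split(pr[, 2L], factor(pr[, 1L], levels = seq_len(n)))
  lapply(nbs, function(v) sort(unique(v)))
}

#' Queen-contiguity spatial weights at cumulative order k
#'
#' Order-1 neighbors are zones sharing any boundary point (edge or corner of
#' any cell). Order-k (cumulative, the default) collects every zone
#' reachable within k adjacency steps, excluding the zone itself; an
#' exclusive variant keeps only zones at exactly k steps.
#'
#' @param zones Integer matrix of zone labels (NA outside the study area).
#' @param order Contiguity order, a positive integer (typically 1-3).
#' @param cumulative If TRUE (default) neighbors within <= order steps,
#'   else exactly at `order` steps.
#' @return An object of class `spatial_weights`: list with `neighbors` (list
#'   of integer vectors), `n`, `order`, `cumulative`. Zones with no order-1
#'   neighbor trigger a warning and keep an empty list (excluded from
#'   inference downstream).
#' @export
queen_weights <- function(zones, order = 1L, cumulative = TRUE) {
  adj <- zone_adjacency(zones)
  n <- length(adj)
  isolated <- which(vapply(adj, length, 1L) == 0L)
  if (length(isolated))
    warning("zones with no queen neighbor excluded from inference: ",
            paste(isolated, collapse = ", "))
  nbs <- adj
  if (order > 1L) {
    nbs <- lapply(seq_len(n), function(i) {
      reached <- i
      frontier <- adj[[i]]
      acc <- frontier
      for (k in seq_len(order - 1L)) {
        reached <- union(reached, frontier)
        frontier <- setdiff(unique(unlist(adj[frontier])), reached)
        if (!length(frontier)) break
        acc <- if (cumulative) union(acc, frontier) else frontier
      }
      sort(setdiff(acc, i))
    })
  }
  structure(list(neighbors = nbs, n = n, order = as.integer(order),
                 cumulative = cumulative),
            class = "spatial_weights")
}

#' Getis-Ord Gi* statistic
#'
#' Standardized local Gi* including the self term (`w_ii = 1`) under binary
#' weights:
#' `z_i = (S_i - xbar * W_i) / (S * sqrt((n * W_i - W_i^2) / (n - 1)))`
#' with `S_i` the sum of the value at i and its neighbors, `W_i` the number
#' of weighted zones (neighbors + self), `xbar` the global mean and `S` the
#' global (population) standard deviation. Zones with missing values are
#' excluded from n and from neighbor sums and get `NA`.
#'
#' @param values Numeric per-zone statistic (e.g., zonal mean travel time).
#' @param weights A [queen_weights()] object.
#' @return Numeric z-value per zone.
#' @export
gi_star <- function(values, weights) {
  n_all <- weights$n
  stopifnot(length(values) == n_all)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 zones with values")
  x <- values
  xbar <- mean(x[ok])
  s <- sqrt(mean(x[ok]^2) - xbar^2)
  if (s == 0) stop("zero variance: all zone values equal")
  z <- rep(NA_real_, n_all)
  for (i in which(ok)) {
    nb <- weights$neighbors[[i]]
    nb <- nb[ok[nb]]
    wi <- length(nb) + 1
    if (wi >= n) next   # neighborhood spans every zone: undefined, NA
    si <- x[i] + sum(x[nb])
    denom <- s * sqrt((n * wi - wi^2) / (n - 1))
    z[i] <- (si - xbar * wi) / denom
  }
  z
}

#' Conditional-permutation pseudo p-values for Gi*
#'
#' Holds each zone's own value fixed and reassigns the remaining values at
#' random among the other zones `n_perm` times;
#' `p_i = (1 + #permutations with |z| >= observed |z|) / (1 + n_perm)`.
#' Deterministic given `seed`.
#'
#' @param values Per-zone values.
#' @param weights A [queen_weights()] object.
#' @param n_perm Number of permutations, at least 999 (default 9999 so that
#'   p <= 0.001 is resolvable).
#' @param seed Integer seed.
#' @return Pseudo p-value per zone (`NA` for zones without values or
#'   neighbors).
#' @export
permutation_p <- function(values, weights, n_perm = 9999, seed = 1L) {
  if (n_perm < 999) stop("n_perm must be at least 999")
  ok <- !is.na(values)
  idx_map <- cumsum(ok)
  nbs_sub <- lapply(which(ok), function(i) {
    nb <- weights$neighbors[[i]]
    as.integer(idx_map[nb[ok[nb]]])
  })
  p <- rep(NA_real_, length(values))
  p[ok] <- withr::with_seed(seed,
    .gistar_perm_p(values[ok], nbs_sub, as.integer(n_perm)))
  p
}

#' Multi-order Gi* cluster labels
#'
#' Runs Gi* with permutation inference at cumulative queen-contiguity
#' orders 1-3 and applies the monotone multi-order rule: a zone is a
#' significant cluster at order k only if its pseudo p-value is at or below
#' `alpha` there AND its |z| exceeds its |z| at every lower order. The
#' reported order is the highest at which the rule holds; the label is
#' `"high"` (long travel times, low access) for positive z and `"low"` for
#' negative z at that order.
#'
#' @param values Per-zone values (e.g., zonal mean minutes).
#' @param zones Zone label raster.
#' @param alpha Significance level (default 0.001).
#' @param n_perm Permutations per order (default 9999).
#' @param seed Integer seed.
#' @param orders Contiguity orders to evaluate (default 1:3).
#' @return Data frame of class `gistar_result`: one row per zone with z and
#'   p per order, `label` in {"high","low","none"} and `order` (NA when
#'   label is "none").
#' @export
multi_order_clusters <- function(values, zones, alpha = 0.001,
                                 n_perm = 9999, seed = 1L, orders = 1:3) {
  zmat <- matrix(NA_real_, length(values), length(orders))
  pmat <- matrix(NA_real_, length(values), length(orders))
  for (j in seq_along(orders)) {
    w <- queen_weights(zones, orders[j])
    zmat[, j] <- gi_star(values, w)
    pmat[, j] <- permutation_p(values, w, n_perm,
                               seed = seed + orders[j])
  }
  label <- rep("none", length(values))
  best_order <- rep(NA_integer_, length(values))
  for (i in seq_along(values)) {
    if (is.na(zmat[i, 1L])) next
    for (j in rev(seq_along(orders))) {
      if (is.na(zmat[i, j])) next
      sig <- !is.na(pmat[i, j]) && pmat[i, j] <= alpha
      monot <- isTRUE(all(abs(zmat[i, j]) >
                            abs(zmat[i, seq_len(j - 1L)])))
      if (sig && monot) {
        best_order[i] <- orders[j]
        label[i] <- if (zmat[i, j] > 0) "high" else "low"
        break
      }
    }
  }
  out <- data.frame(zone = seq_along(values), value = values)
  for (j in seq_along(orders)) out[[paste0("z", orders[j])]] <- zmat[, j]
  for (j in seq_along(orders)) out[[paste0("p", orders[j])]] <- pmat[, j]
  out$label <- label
  out$order <- best_order
  class(out) <- c("gistar_result", "data.frame")
  out
}

#' Zonal mean of a travel-time surface
#'
#' Area mean (population-unweighted) of the finite cell minutes in each
#' zone. Zones containing no finite cells get `NA` with a warning and are
#' later excluded from Gi* inference.
#'
#' @param tt A `travel_time_surface`.
#' @param zones Zone label matrix on the same grid.
#' @return Numeric vector of per-zone mean minutes, indexed by zone id.
#' @export
zonal_mean <- function(tt, zones) {
  stopifnot(all(dim(zones) == dim(tt$minutes)))
  n <- max(zones, na.rm = TRUE)
  v <- tt$minutes
  fin <- is.finite(v)
  sums <- tapply(v[fin], factor(zones[fin], levels = seq_len(n)),
                 mean)
  out <- as.numeric(sums)
  if (anyNA(out))
    warning("zones with no finite travel time set to NA: ",
            paste(which(is.na(out)), collapse = ", "))
  out
}

#' Per-zone summary table for descriptive plots
#'
#' Mean travel time, mean poverty and total population per parish — the
#' table behind access-vs-poverty bubble plots.
#'
#' @param scene A `synthetic_scene`.
#' @param tt A `travel_time_surface` on the scene's grid.
#' @return Data frame with `zone`, `minutes`, `poverty`, `population`.
#' @export
zone_summary <- function(scene, tt) {
  n <- max(scene$parishes, na.rm = TRUE)
  f <- factor(scene$parishes, levels = seq_len(n))
  data.frame(
    zone = seq_len(n),
    minutes = suppressWarnings(zonal_mean(tt, scene$parishes)),
    poverty = as.numeric(tapply(scene$poverty, f, mean)),
    population = as.numeric(tapply(scene$population, f, sum)))
}
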