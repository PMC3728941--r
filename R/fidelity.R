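#' Mean squared distance of a path about its mean center
#'
#' The site-fidelity statistic: the mean of squared planar distances from
#' each path point to the arithmetic mean center of the path. Optional axis
#' weights (used when coordinates are standardised for unequal variance)
#' rescale the squared components.
#'
#' @param points matrix/data.frame of planar coordinates (km), >= 2 rows.
#' @param weights length-2 multipliers applied to the squared x and y
#'   deviations (default unweighted).
#' @return MSD in km^2 (weighted units when `weights` differ from 1).
#' @export
mean_squared_distance <- function(points, weights = c(1, 1)) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2) stop("MSD undefined for fewer than 2 points")
  dev <- sweep(pts, 2, colMeans(pts))
  mean(dev[, 1]^2 * weights[1] + dev[, 2]^2 * weights[2])
}

# Resample environment bathymetry onto a planar km grid covering the walk's
# reachable envelope, for fast constrained-walk lookups.
planar_bathy <- function(env, proj, center, reach_km, cell_km = 1) {
  gx <- seq(center[1] - reach_km, center[1] + reach_km, by = cell_km)
  gy <- seq(center[2] - reach_km, center[2] + reach_km, by = cell_km)
  xy <- expand.grid(x = gx, y = gy)
  ll <- unproject_points(proj, xy$x, xy$y)
  b <- env_extract(env, "bathy", ll$lon, ll$lat)
  list(m = matrix(b, length(gx), length(gy)), x0 = gx[1], y0 = gy[1],
       cell = cell_km)
}

#' One bathymetry-constrained random-walk replicate
#'
#' Keeps the observed step lengths in order, draws each heading uniformly on
#' [0, 2pi), starts from the observed start point, and redraws (up to
#' `max_attempts`, then reflects) any step landing outside the permitted
#' depth band of -100 to 0 m.
#'
#' @param path matrix/data.frame of observed planar coordinates (km).
#' @param env an `env_fields` object (bathymetry constraint).
#' @param proj the [albers_projection()] matching `path`.
#' @param depth_band permitted bathymetry range (m).
#' @param max_attempts heading redraws per step before reflecting.
#' @param bathy_grid optional precomputed [planar_bathy()] grid (reused by
#'   the fidelity test across replicates).
#' @return data.frame of replicate coordinates `x`, `y`; attribute
#'   `violations` counts reflected steps that still ended out of band.
#' @export
constrained_random_walk <- function(path, env, proj,
                                    depth_band = c(-100, 0),
                                    max_attempts = 100, bathy_grid = NULL) {
  pts <- as.matrix(path)[, 1:2, drop = FALSE]
  steps <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  if (is.null(bathy_grid)) {
    reach <- sum(steps) + 5
    bathy_grid <- planar_bathy(env, proj, pts[1, ], reach)
  }
  w <- constrained_rw_cpp(pts[1, 1], pts[1, 2], steps,
                          bathy_grid$m, bathy_grid$x0, bathy_grid$y0,
                          bathy_grid$cell, depth_band[1], depth_band[2],
                          max_attempts)
  out <- data.frame(x = w$x, y = w$y)
  attr(out, "violations") <- w$violations
  out
}

#' Monte-Carlo site-fidelity test
#'
#' Compares the observed path's mean squared distance with those of `n`
#' bathymetry-constrained random walks sharing its step lengths.
#' `proportion_higher` is the percentage of replicates whose MSD exceeds the
#' observed MSD; spatially constrained (site-faithful) movement yields high
#' values. Fidelity is declared at `threshold` (95 = one-sided alpha of
#' 0.05).
#'
#' Coordinate standardization (dividing each axis by the observed path's
#' standard deviation when their ratio exceeds `rescale_trigger`) is
#' available for paths supplied in geographic degrees, whose axes have
#' unequal metric scales. It is off by default: in the equal-area km plane
#' the axes are already commensurate, and weighting by the observed path's
#' own realised shape breaks the exchangeability of observed and replicate
#' paths under the null (random walks are characteristically elongated),
#' inflating the rejection rate.
#'
#' @param path observed planar path (km), >= 10 points (e.g. projected mean
#'   daily locations at a foraging site).
#' @param env an `env_fields` object.
#' @param proj the matching [albers_projection()].
#' @param n number of random-walk replicates.
#' @param threshold fidelity verdict threshold on `proportion_higher`.
#' @param depth_band permitted bathymetry range (m) for the walks.
#' @param rescale_trigger sd ratio beyond which axes are standardised.
#' @param seed optional seed for the replicate draws.
#' @return An object of class `fidelity_result`: list with `msd_observed`,
#'   `msd_replicates`, `proportion_higher` (percent), `fidelity` (logical),
#'   `n`, `standardized`.
#' @export
site_fidelity_test <- function(path, env, proj, n = 100, threshold = 95,
                               depth_band = c(-100, 0),
                               rescale_trigger = Inf, seed = NULL) {
  pts <- as.matrix(path)[, 1:2, drop = FALSE]
  if (nrow(pts) < 10) stop("need at least 10 path points for the fidelity test")
  sdx <- stats::sd(pts[, 1]); sdy <- stats::sd(pts[, 2])
  ratio <- max(sdx, sdy) / max(min(sdx, sdy), 1e-12)
  standardized <- is.finite(ratio) && ratio > rescale_trigger
  wts <- if (standardized) 1 / c(sdx^2, sdy^2) else c(1, 1)
  steps <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  grid <- planar_bathy(env, proj, pts[1, ], sum(steps) + 5)
  obs <- mean_squared_distance(pts, wts)
  reps <- with_seed(seed, vapply(seq_len(n), function(i) {
    w <- constrained_random_walk(pts, env, proj, depth_band,
                                 bathy_grid = grid)
    mean_squared_distance(w, wts)
  }, numeric(1)))
  prop <- 100 * sum(reps > obs) / n
  structure(list(msd_observed = obs, msd_replicates = reps,
                 proportion_higher = prop, fidelity = prop >= threshold,
                 threshold = threshold, n = n, standardized = standardized),
            class = "fidelity_result")
}
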