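#' Build the 25 x 25 km analysis grid inside the 100-m isobath
#'
#' Lays a regular lattice of `cell_km` square cells over the projected
#' domain (or a supplied planar bounding box) and keeps cells containing
#' water no deeper than `depth_limit_m`: a 3 x 3 subsample of each cell is
#' tested and the cell is retained when any subpoint is in-band water.
#' Environmental covariates are sampled at the cell center.
#'
#' @param env an `env_fields` object.
#' @param proj the [albers_projection()] defining the plane.
#' @param cell_km cell side length (km).
#' @param depth_limit_m isobath bound (positive metres).
#' @param release_points optional data.frame/matrix of release lon/lat; the
#'   `dist_release_km` covariate is the distance from the cell center to the
#'   mean release location.
#' @param bbox optional planar bounding box c(xmin, xmax, ymin, ymax) (km);
#'   defaults to the projected raster domain.
#' @return data.frame of retained cells: `cell`, planar center `x`, `y`,
#'   `lon`, `lat`, `bathy_m`, `sst_c`, `npp`, `dist_mainland_km`,
#'   `dist_release_km`; attribute `cell_km`.
#' @export
build_grid <- function(env, proj = env$proj, cell_km = 25, depth_limit_m = 100,
                       release_points = NULL, bbox = NULL) {
  if (is.null(bbox)) {
    corners <- expand.grid(lon = c(env$lon_range, mean(env$lon_range)),
                           lat = c(env$lat_range, mean(env$lat_range)))
    pc <- project_points(proj, corners$lon, corners$lat)
    bbox <- c(min(pc$x), max(pc$x), min(pc$y), max(pc$y))
  }
  nx <- floor((bbox[2] - bbox[1]) / cell_km)
  ny <- floor((bbox[4] - bbox[3]) / cell_km)
  if (nx < 1 || ny < 1) stop("domain smaller than one grid cell")
  cx <- bbox[1] + (seq_len(nx) - 0.5) * cell_km
  cy <- bbox[3] + (seq_len(ny) - 0.5) * cell_km
  cells <- expand.grid(x = cx, y = cy)
  off <- cell_km * c(-1, 0, 1) / 3
  sub <- expand.grid(ox = off, oy = off)
  in_band <- rep(FALSE, nrow(cells))
  for (s in seq_len(nrow(sub))) {
    ll <- unproject_points(proj, cells$x + sub$ox[s], cells$y + sub$oy[s])
    b <- env_extract(env, "bathy", ll$lon, ll$lat)
    in_band <- in_band | (!is.na(b) & b < 0 & b >= -depth_limit_m)
  }
  cells <- cells[in_band, , drop = FALSE]
  if (nrow(cells) == 0) stop("no grid cells intersect the permitted isobath band")
  ll <- unproject_points(proj, cells$x, cells$y)
  out <- data.frame(cell = seq_len(nrow(cells)), x = cells$x, y = cells$y,
                    lon = ll$lon, lat = ll$lat,
                    bathy_m = env_extract(env, "bathy", ll$lon, ll$lat),
                    sst_c = env_extract(env, "sst", ll$lon, ll$lat),
                    npp = env_extract(env, "npp", ll$lon, ll$lat))
  land <- c(list(env$mainland), env$islands)
  out$dist_mainland_km <- distance_to_polygon_km(out$lon, out$lat,
                                                 env$mainland, proj)
  if (!is.null(release_points)) {
    rp <- as.matrix(release_points)
    mr <- colMeans(rp)
    out$dist_release_km <- great_circle_km(out$lon, out$lat, mr[1], mr[2])
  } else out$dist_release_km <- NA_real_
  attr(out, "cell_km") <- cell_km
  attr(out, "bbox") <- bbox
  rownames(out) <- NULL
  out
}

#' Count turtle foraging days per grid cell
#'
#' Each mean daily foraging location contributes one turtle-day to the cell
#' containing it; locations from foraging periods shorter than
#' `min_period_days` are excluded, and counts are pooled over animals.
#'
#' @param daily data.frame of mean daily foraging locations with columns
#'   `lon`, `lat` and `period_days` (duration of the location's foraging
#'   period).
#' @param grid output of [build_grid()].
#' @param proj the matching projection.
#' @param min_period_days exclusion threshold for brief foraging periods.
#' @return `grid` with an added integer column `days`; attribute `n_dropped`
#'   counts qualifying locations falling outside the grid.
#' @export
count_foraging_days <- function(daily, grid, proj, min_period_days = 2) {
  cell_km <- attr(grid, "cell_km")
  bbox <- attr(grid, "bbox")
  grid$days <- 0L
  keep <- daily$period_days >= min_period_days
  pts <- daily[keep, , drop = FALSE]
  n_dropped <- 0L
  if (nrow(pts) > 0) {
    pp <- project_points(proj, pts$lon, pts$lat)
    ix <- floor((pp$x - bbox[1]) / cell_km)
    iy <- floor((pp$y - bbox[3]) / cell_km)
    key <- paste(floor((grid$x - bbox[1]) / cell_km),
                 floor((grid$y - bbox[3]) / cell_km))
    pkey <- paste(ix, iy)
    hit <- match(pkey, key)
    n_dropped <- sum(is.na(hit))
    if (n_dropped > 0)
      warning(n_dropped, " foraging locations outside the grid dropped")
    tab <- table(hit[!is.na(hit)])
    grid$days[as.integer(names(tab))] <- as.integer(tab)
  }
  attr(grid, "n_dropped") <- n_dropped
  grid
}

#' Randomly subsample grid cells
#'
#' Draws floor(fraction x n) cells uniformly without replacement, the
#' device used to limit spatial correlation between neighbouring cells
#' before regression.
#'
#' @param grid a grid data.frame.
#' @param fraction sampling fraction in (0, 1].
#' @param seed optional seed.
#' @return the sampled subset of `grid`.
#' @export
subsample_cells <- function(grid, fraction = 0.2, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nrow(grid)
  k <- floor(fraction * n)
  idx <- with_seed(seed, sample.int(n, k))
  grid[sort(idx), , drop = FALSE]
}

#' Log-link GLM of foraging days on environmental covariates
#'
#' Fits foraging days per cell against distance to release, distance to the
#' mainland shore, annual SST, bathymetry and NPP with a log link. The
#' default family is Poisson with Pearson overdispersion scaling
#' (quasipoisson); a log-normal alternative (Gaussian on log(days + 1)) is
#' available. Reports per-coefficient Wald statistics: estimate, SE, 95% CI,
#' chi-square and p-value.
#'
#' @param cells grid data.frame with columns `days`, `dist_release_km`,
#'   `dist_mainland_km`, `sst_c`, `bathy_m`, `npp`.
#' @param family "quasipoisson" or "lognormal".
#' @return list of class `habitat_glm`: `table` (coefficient report),
#'   `fit` (the glm/lm object), `family`.
#' @export
fit_log_glm <- function(cells, family = c("quasipoisson", "lognormal")) {
  family <- match.arg(family)
  if (nrow(cells) < 20) stop("need at least 20 cells for the regression")
  covs <- c("dist_release_km", "dist_mainland_km", "sst_c", "bathy_m", "npp")
  if (!all(c("days", covs) %in% names(cells)))
    stop("cells must contain 'days' and the five covariates")
  if (!all(is.finite(as.matrix(cells[, covs]))))
    stop("non-finite covariate values")
  fml <- stats::reformulate(covs, response = if (family == "quasipoisson")
    "days" else "log(days + 1)")
  fit <- if (family == "quasipoisson") {
    stats::glm(fml, data = cells, family = stats::quasipoisson(link = "log"))
  } else stats::lm(fml, data = cells)
  if (family == "quasipoisson" && !fit$converged)
    stop("GLM failed to converge (separation or non-finite deviance)")
  cf <- summary(fit)$coefficients
  est <- cf[, 1]; se <- cf[, 2]
  chisq <- (est / se)^2
  out <- data.frame(parameter = rownames(cf), estimate = est, se = se,
                    lower_ci = est - 1.96 * se, upper_ci = est + 1.96 * se,
                    chi_square = chisq,
                    p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
                    row.names = NULL)
  structure(list(table = out, fit = fit, family = family),
            class = "habitat_glm")
}
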