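#' Generate synthetic environmental fields over a shelf-sea domain
#'
#' Builds a set of co-registered lon/lat rasters — bathymetry (m, negative at
#' sea, positive on land), annual mean sea-surface temperature (deg C) and net
#' primary production (mg C/m^2/day) — together with a mainland polygon, an
#' optional barrier island, and the coastline. The domain emulates a northern
#' Gulf-of-Mexico-style shelf: a smooth east-west coastline with depth
#' increasing monotonically offshore, temperature warming southwards, and
#' productivity highest nearshore. The barrier island makes "nearest land"
#' and "mainland" distances genuinely different quantities.
#'
#' All randomness (coastline perturbation, SST/NPP texture) is governed by
#' `seed`; the same seed yields bit-identical fields.
#'
#' @param lon_range,lat_range numeric length-2 domain bounds (decimal degrees).
#' @param res_deg raster resolution in degrees.
#' @param seed integer seed, or NULL to use the ambient RNG stream.
#' @param barrier_island logical; add a thin offshore island to the coastline.
#' @param proj an [albers_projection()] used for km-scale geometry.
#' @return An object of class `env_fields`: list with cell-centre coordinate
#'   vectors `lon`, `lat`, matrices `bathy`, `sst`, `npp` (dim nlon x nlat),
#'   `mainland` polygon, `islands` (list of polygons), `coast` (data.frame of
#'   the coastline curve), and `proj`.
#' @export
generate_environment <- function(lon_range = c(-97.8, -88),
                                 lat_range = c(24, 30.2),
                                 res_deg = 0.05,
                                 seed = NULL,
                                 barrier_island = TRUE,
                                 proj = albers_projection()) {
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0)
    stop("degenerate domain: lon_range and lat_range must have positive extent")
  with_seed(seed, {
    lon <- seq(lon_range[1] + res_deg / 2, lon_range[2] - res_deg / 2, by = res_deg)
    lat <- seq(lat_range[1] + res_deg / 2, lat_range[2] - res_deg / 2, by = res_deg)
    nlon <- length(lon); nlat <- length(lat)

    # Coastline: lat = f(lon), a smooth seeded perturbation of a sine curve,
    # land to the north. Stored as a dense curve for interpolation.
    span <- diff(lon_range)
    base_lat <- lat_range[2] - 0.15 * diff(lat_range)
    kx <- seq(lon_range[1], lon_range[2], length.out = 9)
    ky <- stats::rnorm(9, 0, 0.12)
    fcoast <- stats::splinefun(kx, base_lat +
                                 0.3 * sin(2 * pi * (kx - lon_range[1]) / span) + ky,
                               method = "natural")
    coast_lon <- seq(lon_range[1], lon_range[2], by = res_deg / 4)
    coast <- data.frame(lon = coast_lon, lat = fcoast(coast_lon))

    # Signed offshore distance (km) of every cell centre from the coastline.
    cp <- project_points(proj, coast$lon, coast$lat)
    grid_lon <- rep(lon, times = nlat)
    grid_lat <- rep(lat, each = nlon)
    gp <- project_points(proj, grid_lon, grid_lat)
    dmin <- rep(Inf, length(grid_lon))
    for (i in seq_len(nrow(cp))) {
      d2 <- (gp$x - cp$x[i])^2 + (gp$y - cp$y[i])^2
      dmin <- pmin(dmin, d2)
    }
    dist_coast <- sqrt(dmin)
    on_land <- grid_lat > fcoast(grid_lon)

    # Bathymetry: gently sloping shelf; depth(d) = -0.115 d^1.35 puts the
    # 100-m isobath roughly 150 km offshore. Land rises 0.5 m per km inland.
    elev <- ifelse(on_land, 0.5 * dist_coast, -0.115 * dist_coast^1.35)
    elev[!on_land] <- pmin(elev[!on_land], -0.01)

    islands <- list()
    if (barrier_island) {
      is_lon <- lon_range[1] + span * c(0.25, 0.45)
      taper <- function(l) {
        u <- (l - is_lon[1]) / diff(is_lon)
        ifelse(u > 0 & u < 1, sin(pi * u), 0)
      }
      ctr <- fcoast(grid_lon) - 0.35
      half <- 0.028 * taper(grid_lon)
      bump <- ifelse(half > 0 & abs(grid_lat - ctr) < half,
                     2.5 * (1 - (abs(grid_lat - ctr) / half)^2), 0)
      elev <- pmax(elev, ifelse(bump > 0, bump, -Inf))
      il <- seq(is_lon[1], is_lon[2], length.out = 60)
      hw <- 0.028 * sin(pi * seq(0, 1, length.out = 60))
      islands <- list(list(lon = c(il, rev(il)),
                           lat = c(fcoast(il) - 0.35 + hw,
                                   rev(fcoast(il) - 0.35 - hw))))
    }
    bathy <- matrix(elev, nlon, nlat)

    # SST: southwards-warming gradient plus smooth texture.
    sst <- 24.3 + 0.45 * (lat_range[2] - grid_lat) +
      smooth_field(nlon, nlat, sd = 0.35)
    sst <- matrix(sst, nlon, nlat)

    # NPP: nearshore-enriched, decaying offshore, plus smooth texture.
    npp <- 4300 * exp(-pmax(dist_coast * ifelse(on_land, 0, 1), 0) / 250) +
      smooth_field(nlon, nlat, sd = 250)
    npp <- matrix(pmax(npp, 150), nlon, nlat)

    ml <- seq(lon_range[1], lon_range[2], by = res_deg)
    mainland <- list(lon = c(ml, lon_range[2], lon_range[1]),
                     lat = c(fcoast(ml), lat_range[2] + 0.5, lat_range[2] + 0.5))

    structure(list(lon = lon, lat = lat, res_deg = res_deg,
                   bathy = bathy, sst = sst, npp = npp,
                   mainland = mainland, islands = islands,
                   coast = coast, proj = proj,
                   lon_range = lon_range, lat_range = lat_range),
              class = "env_fields")
  })
}

# Smooth Gaussian texture: coarse white noise bilinearly upsampled, returned
# as a vector in grid order (lon fastest).
smooth_field <- function(nlon, nlat, coarse = 10, sd = 1) {
  cz <- matrix(stats::rnorm((coarse + 1)^2, 0, sd), coarse + 1, coarse + 1)
  ix <- seq(1, coarse + 1, length.out = nlon)
  iy <- seq(1, coarse + 1, length.out = nlat)
  i0 <- pmin(floor(ix), coarse); fx <- ix - i0
  j0 <- pmin(floor(iy), coarse); fy <- iy - j0
  out <- matrix(0, nlon, nlat)
  for (j in seq_len(nlat)) {
    a <- cz[cbind(i0, j0[j])] * (1 - fx) + cz[cbind(i0 + 1, j0[j])] * fx
    b <- cz[cbind(i0, j0[j] + 1)] * (1 - fx) + cz[cbind(i0 + 1, j0[j] + 1)] * fx
    out[, j] <- a * (1 - fy[j]) + b * fy[j]
  }
  as.vector(out)
}

#' Extract raster values at point locations
#'
#' Bilinear interpolation of an `env_fields` layer at arbitrary lon/lat
#' positions. Points outside the raster return NA.
#'
#' @param env an `env_fields` object.
#' @param layer one of "bathy", "sst", "npp".
#' @param lon,lat coordinate vectors.
#' @return numeric vector of interpolated values.
#' @export
env_extract <- function(env, layer = c("bathy", "sst", "npp"), lon, lat) {
  layer <- match.arg(layer)
  m <- env[[layer]]
  fx <- (lon - env$lon[1]) / env$res_deg + 1
  fy <- (lat - env$lat[1]) / env$res_deg + 1
  nlon <- length(env$lon); nlat <- length(env$lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(fx) & !is.na(fy) & fx >= 1 & fx <= nlon & fy >= 1 & fy <= nlat
  if (any(ok)) {
    i0 <- pmin(floor(fx[ok]), nlon - 1); wx <- fx[ok] - i0
    j0 <- pmin(floor(fy[ok]), nlat - 1); wy <- fy[ok] - j0
    v <- m[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
      m[cbind(i0 + 1, j0)] * wx * (1 - wy) +
      m[cbind(i0, j0 + 1)] * (1 - wx) * wy +
      m[cbind(i0 + 1, j0 + 1)] * wx * wy
    out[ok] <- v
  }
  out
}

#' Write an `env_fields` raster layer as an ESRI ASCII grid
#'
#' @param env an `env_fields` object.
#' @param layer one of "bathy", "sst", "npp".
#' @param path output file path.
#' @export
write_ascii_grid <- function(env, layer, path) {
  m <- env[[layer]]
  nlon <- length(env$lon); nlat <- length(env$lat)
  hdr <- c(sprintf("ncols %d", nlon),
           sprintf("nrows %d", nlat),
           sprintf("xllcorner %.10f", env$lon[1] - env$res_deg / 2),
           sprintf("yllcorner %.10f", env$lat[1] - env$res_deg / 2),
           sprintf("cellsize %.10f", env$res_deg),
           "NODATA_value -9999")
  rows <- vapply(rev(seq_len(nlat)), function(j)
    paste(formatC(m[, j], format = "g", digits = 8), collapse = " "),
    character(1))
  writeLines(c(hdr, rows), path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path file path.
#' @return list with `lon`, `lat` cell-centre vectors and `values` matrix
#'   (nlon x nlat).
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path)
  hv <- function(k) as.numeric(strsplit(trimws(ln[k]), "\\s+")[[1]][2])
  ncols <- hv(1); nrows <- hv(2)
  xll <- hv(3); yll <- hv(4); cs <- hv(5)
  vals <- scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = ncols)        # columns are raster rows, N to S
  m <- m[, rev(seq_len(nrows)), drop = FALSE]
  list(lon = xll + cs * (seq_len(ncols) - 0.5),
       lat = yll + cs * (seq_len(nrows) - 0.5),
       values = m)
}

#' Write polygons as GeoJSON
#'
#' @param polygons a single polygon (list with `lon`, `lat`) or a list of them.
#' @param path output file path.
#' @export
write_geojson_polygons <- function(polygons, path) {
  if (!is.null(polygons$lon)) polygons <- list(polygons)
  feats <- lapply(polygons, function(p) {
    ring <- cbind(p$lon, p$lat)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
}

#' Read polygons from GeoJSON
#'
#' @param path file path.
#' @return list of polygons, each a list with `lon` and `lat`.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geoms <- gj$features$geometry
  lapply(seq_along(geoms$type), function(i) {
    ring <- geoms$coordinates[[i]]
    if (is.list(ring)) ring <- ring[[1]]
    if (length(dim(ring)) == 3) ring <- ring[1, , ]
    list(lon = ring[, 1], lat = ring[, 2])
  })
}
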