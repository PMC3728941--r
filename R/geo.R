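#' Spherical Albers equal-area projection
#'
#' Defines a meter-based (here km-based) equal-area plane used for all kernel
#' density areas, mean-squared-distance computations, and the 25-km analysis
#' grid. Equal-area is required so that km^2 areas read off the plane are
#' faithful. The default is centred on the Gulf of Mexico.
#'
#' @param lon0,lat0 projection centre (decimal degrees).
#' @param lat1,lat2 standard parallels (decimal degrees).
#' @param radius_km spherical Earth radius in km.
#' @return An object of class `albers_proj`.
#' @examples
#' prj <- albers_projection()
#' xy <- project_points(prj, -90, 25)   # centre maps to (0, 0)
#' @export
albers_projection <- function(lon0 = -90, lat0 = 25, lat1 = 20, lat2 = 30,
                              radius_km = 6371) {
  phi0 <- lat0 * pi / 180
  phi1 <- lat1 * pi / 180
  phi2 <- lat2 * pi / 180
  n <- (sin(phi1) + sin(phi2)) / 2
  if (abs(n) < 1e-12) stop("standard parallels may not be symmetric about the equator")
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho0 <- radius_km / n * sqrt(C - 2 * n * sin(phi0))
  structure(list(lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2,
                 n = n, C = C, rho0 = rho0, R = radius_km),
            class = "albers_proj")
}

#' Project lon/lat to the equal-area plane (km)
#'
#' @param proj an `albers_proj` object.
#' @param lon,lat coordinate vectors in decimal degrees.
#' @return A data.frame with columns `x`, `y` in km.
#' @export
project_points <- function(proj, lon, lat) {
  stopifnot(inherits(proj, "albers_proj"))
  phi <- lat * pi / 180
  lam <- (lon - proj$lon0) * pi / 180
  rho <- proj$R / proj$n * sqrt(proj$C - 2 * proj$n * sin(phi))
  th <- proj$n * lam
  data.frame(x = rho * sin(th), y = proj$rho0 - rho * cos(th))
}

#' Inverse Albers projection: plane (km) back to lon/lat
#'
#' @param proj an `albers_proj` object.
#' @param x,y planar coordinates in km.
#' @return A data.frame with columns `lon`, `lat`.
#' @export
unproject_points <- function(proj, x, y) {
  stopifnot(inherits(proj, "albers_proj"))
  rho <- sqrt(x^2 + (proj$rho0 - y)^2)
  th <- atan2(x, proj$rho0 - y)
  s <- (proj$C - (rho * proj$n / proj$R)^2) / (2 * proj$n)
  s <- pmin(1, pmax(-1, s))
  data.frame(lon = proj$lon0 + th / proj$n * 180 / pi,
             lat = asin(s) * 180 / pi)
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised).
#' @return distances in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates (vectors, same plane/units as the ring).
#' @param ring_x,ring_y polygon ring vertices (closed implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring_x, ring_y) {
  nv <- length(ring_x)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- ring_x[i]; yi <- ring_y[i]
    xj <- ring_x[j]; yj <- ring_y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Minimum distance from one point to a set of segments in the plane.
point_segments_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  cx <- x1 + t * dx; cy <- y1 + t * dy
  min(sqrt((px - cx)^2 + (py - cy)^2))
}

#' Distance from a point to a polygon, in km
#'
#' Points and polygon are projected to the equal-area plane; the minimum
#' point-to-boundary distance is returned, or 0 for points inside the polygon.
#'
#' @param lon,lat point coordinates (vectors) in decimal degrees.
#' @param polygon a list with numeric `lon` and `lat` ring vectors.
#' @param proj an `albers_proj` object.
#' @return distances in km (0 inside the polygon).
#' @export
distance_to_polygon_km <- function(lon, lat, polygon, proj) {
  if (is.null(polygon$lon) || length(polygon$lon) < 3)
    stop("invalid polygon: need a ring of at least 3 vertices")
  ring <- project_points(proj, polygon$lon, polygon$lat)
  pts <- project_points(proj, lon, lat)
  nv <- nrow(ring)
  x1 <- ring$x; y1 <- ring$y
  x2 <- ring$x[c(2:nv, 1)]; y2 <- ring$y[c(2:nv, 1)]
  d <- vapply(seq_len(nrow(pts)), function(i) {
    point_segments_dist(pts$x[i], pts$y[i], x1, y1, x2, y2)
  }, numeric(1))
  inside <- point_in_polygon(pts$x, pts$y, ring$x, ring$y)
  d[inside] <- 0
  d
}

#' Distance from a point to the nearest of several polygons, in km
#'
#' Used for "nearest land" when the coastline includes barrier islands in
#' addition to the mainland.
#'
#' @param lon,lat point coordinates.
#' @param polygons a list of polygons (each a list with `lon`, `lat`).
#' @param proj an `albers_proj` object.
#' @return distances in km.
#' @export
distance_to_polygons_km <- function(lon, lat, polygons, proj) {
  d <- sapply(polygons, function(p) distance_to_polygon_km(lon, lat, p, proj))
  if (is.null(dim(d))) min(d) else apply(d, 1, min)
}

# Shoelace area (planar units^2) and area centroid of a ring.
polygon_area_centroid <- function(x, y) {
  nv <- length(x)
  x2 <- x[c(2:nv, 1)]; y2 <- y[c(2:nv, 1)]
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    list(area = 0, cx = mean(x), cy = mean(y))
  } else {
    list(area = abs(a),
         cx = sum((x + x2) * cr) / (6 * a),
         cy = sum((y + y2) * cr) / (6 * a))
  }
}
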