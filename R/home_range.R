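#' Least-squares cross-validation bandwidth for a Gaussian kernel
#'
#' Minimises the closed-form LSCV score of the bivariate Gaussian product
#' kernel over a common smoothing factor h. When the coordinate standard
#' deviations are unequal (ratio above `rescale_trigger`) the data are
#' standardised per axis before scoring and the selected h is back-scaled,
#' giving per-axis bandwidths. If the score is monotone over the search
#' window (no interior minimum), the normal-reference bandwidth is returned
#' with a warning.
#'
#' @param points matrix or data.frame of planar coordinates (km), >= 10 rows.
#' @param rescale_trigger sd ratio beyond which axes are standardised.
#' @param search multiplicative search window around the reference bandwidth.
#' @return list with `h` (length-2 per-axis bandwidth, km), `h_factor` (the
#'   common factor on the standardised scale), `score`, `rescaled`,
#'   `fallback` (TRUE when the reference rule was used).
#' @export
lscv_bandwidth <- function(points, rescale_trigger = 1.5,
                           search = c(0.05, 3)) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 10) stop("need at least 10 points for cross-validation")
  sdx <- stats::sd(pts[, 1]); sdy <- stats::sd(pts[, 2])
  if (sdx == 0 && sdy == 0) stop("degenerate input: all points identical")
  ratio <- max(sdx, sdy) / max(min(sdx, sdy), 1e-12)
  rescaled <- is.finite(ratio) && ratio > rescale_trigger
  scale <- if (rescaled) c(sdx, sdy) else rep(sqrt((sdx^2 + sdy^2) / 2), 2)
  z <- sweep(pts, 2, scale, "/")
  dx2 <- outer(z[, 1], z[, 1], "-")^2
  dy2 <- outer(z[, 2], z[, 2], "-")^2
  href <- 1.06 * n^(-1 / 5)                 # sd ~ 1 after scaling
  off <- upper.tri(dx2)
  sx2 <- dx2[off]; sy2 <- dy2[off]
  score <- function(h) {
    h2 <- h * h
    int_term <- (n + 2 * sum(exp(-(sx2 + sy2) / (4 * h2)))) / (n^2 * 4 * pi * h2)
    loo <- 2 * sum(exp(-(sx2 + sy2) / (2 * h2))) / (n * (n - 1) * 2 * pi * h2)
    int_term - 2 * loo
  }
  # the score can diverge to -Inf as h -> 0 when duplicate (or near-
  # duplicate) coordinates are present, so the minimiser is taken as the
  # best interior local minimum on a log-spaced grid, then refined
  hs <- href * exp(seq(log(search[1]), log(search[2]), length.out = 60))
  sc <- vapply(hs, score, numeric(1))
  interior <- which(diff(sign(diff(sc))) > 0) + 1
  if (length(interior) == 0) {
    warning("LSCV score has no interior minimum over the search window; ",
            "using reference bandwidth")
    h_factor <- href
    fallback <- TRUE
  } else {
    i <- interior[which.min(sc[interior])]
    opt <- stats::optimize(score, interval = hs[c(i - 1, i + 1)])
    h_factor <- opt$minimum
    fallback <- FALSE
  }
  list(h = h_factor * scale, h_factor = h_factor, score = score(h_factor),
       rescaled = rescaled, fallback = fallback)
}

# Evaluate the Gaussian-kernel density on a regular planar grid (or on
# explicitly supplied grid vectors).
kde_evaluate <- function(pts, h, pad = 3.5, res_factor = 4,
                         gx = NULL, gy = NULL) {
  cell <- min(h) / res_factor
  if (is.null(gx))
    gx <- seq(min(pts[, 1]) - pad * h[1], max(pts[, 1]) + pad * h[1], by = cell)
  if (is.null(gy))
    gy <- seq(min(pts[, 2]) - pad * h[2], max(pts[, 2]) + pad * h[2], by = cell)
  Dx <- exp(-outer(gx, pts[, 1], "-")^2 / (2 * h[1]^2))
  Dy <- exp(-outer(gy, pts[, 2], "-")^2 / (2 * h[2]^2))
  dens <- Dx %*% t(Dy) / (nrow(pts) * 2 * pi * h[1] * h[2])
  list(x = gx, y = gy, z = dens, cell = cell)
}

#' Kernel core-area polygon and in-water area
#'
#' Evaluates the fixed-kernel density of the supplied points on a planar grid
#' (resolution bandwidth/4), finds the probability contour holding
#' `probability` of the total mass by sorting cell masses, and reports the
#' in-water area of that region together with its connected activity centers.
#' Thresholding happens before water clipping; the clip then removes any land
#' portion of the region.
#'
#' @param points planar coordinates (km), e.g. projected mean daily locations.
#' @param h per-axis bandwidth (km), e.g. from [lscv_bandwidth()].
#' @param water_fn optional function(x, y) -> logical "is water", in the same
#'   planar coordinates; NULL treats everything as water.
#' @param probability contour probability level (0.5 = core area).
#' @return An object of class `core_area`: list with `area_km2` (in-water),
#'   `area_unclipped_km2`, `centers` (per activity center: cells, mass,
#'   area, centroid x/y), `threshold`, `grid` (density grid), `h`, `mass_in`
#'   (density mass inside the contour before clipping).
#' @export
kde_core_area <- function(points, h, water_fn = NULL, probability = 0.5) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (length(h) == 1) h <- c(h, h)
  if (any(h <= 0)) stop("bandwidth must be positive")
  g <- kde_evaluate(pts, h)
  mass <- g$z * g$cell^2
  total <- sum(mass)
  ord <- order(g$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= probability * total)[1]
  if (is.na(k)) stop("empty contour: pathological bandwidth")
  threshold <- g$z[ord[k]]
  inside <- g$z >= threshold
  mass_in <- sum(mass[inside]) / total

  water <- if (is.null(water_fn)) inside else {
    xy <- expand.grid(x = g$x, y = g$y)
    inside & matrix(water_fn(xy$x, xy$y), length(g$x), length(g$y))
  }
  area_unclipped <- sum(inside) * g$cell^2
  area <- sum(water) * g$cell^2

  centers <- label_components(inside, g, mass)
  structure(list(area_km2 = area, area_unclipped_km2 = area_unclipped,
                 centers = centers, threshold = threshold,
                 mass_in = mass_in, grid = g, h = h,
                 probability = probability, n_points = nrow(pts)),
            class = "core_area")
}

# 4-connected components of the above-threshold region; per-component mass,
# area and mass-weighted centroid.
label_components <- function(inside, g, mass) {
  nx <- length(g$x); ny <- length(g$y)
  lab <- matrix(0L, nx, ny)
  comp <- 0L
  res <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!inside[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- comp
    cells <- matrix(c(i, j), 1)
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- cur[1] + d[1]; jj <- cur[2] + d[2]
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
            inside[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- comp
          queue <- rbind(queue, c(ii, jj))
          cells <- rbind(cells, c(ii, jj))
        }
      }
    }
    m <- mass[cells]
    res[[comp]] <- data.frame(
      center = comp, n_cells = nrow(cells),
      area_km2 = nrow(cells) * g$cell^2, mass = sum(m),
      cx = sum(g$x[cells[, 1]] * m) / sum(m),
      cy = sum(g$y[cells[, 2]] * m) / sum(m))
  }
  do.call(rbind, res)
}

#' Centroid of the largest activity center
#'
#' When a core area comprises multiple disjoint activity centers, the
#' reported site centroid is the (mass-weighted) centroid of the largest
#' center by area.
#'
#' @param core a `core_area` object.
#' @param proj optional [albers_projection()]; when supplied the centroid is
#'   returned in lon/lat, otherwise in planar km.
#' @return named numeric vector (`lon`/`lat`, or `x`/`y`).
#' @export
largest_center_centroid <- function(core, proj = NULL) {
  if (is.null(core$centers) || nrow(core$centers) == 0)
    stop("core area has no activity centers")
  top <- core$centers[which.max(core$centers$area_km2), ]
  if (is.null(proj)) return(c(x = top$cx, y = top$cy))
  ll <- unproject_points(proj, top$cx, top$cy)
  c(lon = ll$lon, lat = ll$lat)
}
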