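# Shared fixtures, built once per test run.

# Small shelf environment (3 x 3.4 degrees) used by spatial tests.
test_env <- local({
  env <- NULL
  function() {
    if (is.null(env))
      env <<- generate_environment(lon_range = c(-94, -91),
                                   lat_range = c(26.5, 29.9),
                                   res_deg = 0.05, seed = 42,
                                   barrier_island = TRUE)
    env
  }
})

# A bare-bones environment with analytically known bathymetry: depth is
# constant `depth` everywhere, no land. Good for grid-counting tests.
flat_env <- function(depth = -50, lon_range = c(-95, -89),
                     lat_range = c(24, 30)) {
  lon <- seq(lon_range[1] + 0.05, lon_range[2] - 0.05, by = 0.1)
  lat <- seq(lat_range[1] + 0.05, lat_range[2] - 0.05, by = 0.1)
  structure(list(
    lon = lon, lat = lat, res_deg = 0.1,
    bathy = matrix(depth, length(lon), length(lat)),
    sst = matrix(25, length(lon), length(lat)),
    npp = matrix(3000, length(lon), length(lat)),
    mainland = list(lon = c(lon_range[1], lon_range[2], lon_range[2],
                            lon_range[1]),
                    lat = c(lat_range[2] + 0.2, lat_range[2] + 0.2,
                            lat_range[2] + 1, lat_range[2] + 1)),
    islands = list(),
    coast = data.frame(lon = lon, lat = lat_range[2] + 0.2),
    proj = albers_projection(),
    lon_range = lon_range, lat_range = lat_range),
    class = "env_fields")
}

# A start point in comfortably shallow water (~0.45 degrees off the coast).
shallow_start <- function(env, lon = mean(env$lon_range), dlat = 0.45) {
  lat <- stats::approx(env$coast$lon, env$coast$lat, lon)$y - dlat
  p <- project_points(env$proj, lon, lat)
  c(p$x, p$y)
}

# A simple synthetic track data.frame at fixed timestamps.
make_track <- function(lon, lat, lc = "3", id = "t1",
                       t0 = as.POSIXct("2010-06-01 00:00:00", tz = "UTC"),
                       dt_hours = 6) {
  n <- length(lon)
  data.frame(turtle_id = id,
             time = t0 + (seq_len(n) - 1) * dt_hours * 3600,
             lon = lon, lat = lat, lc = rep_len(lc, n),
             stringsAsFactors = FALSE)
}
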