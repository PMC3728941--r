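test_that("invalid simulator configurations are rejected with messages", {
  expect_error(sim_config(duration_range = c(0, 0)), "positive")
  expect_error(sim_config(gamma_migration = 0.2, gamma_foraging = 0.8),
               "identifiable")
  expect_error(sim_config(switch_matrix = matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
                                                 byrow = TRUE)),
               "sum to 1")
  expect_error(sim_config(lc_probs = c(`3` = 1, `2` = 1, `1` = 0, `0` = 0,
                                       A = 0, B = 0)), "probability")
  cfg <- sim_config(seed = 1)
  expect_error(simulate_true_track(cfg, duration_days = -5), "duration")
})

test_that("persistence-free, uniform-turn steps have uncorrelated headings", {
  cfg <- sim_config(gamma_migration = 1e-9, gamma_foraging = 0,
                    turn_concentration = c(0, 0), seed = 5)
  tr <- simulate_true_track(cfg, duration_days = 1000)
  p <- project_points(albers_projection(), tr$lon, tr$lat)
  head <- atan2(diff(p$y), diff(p$x))
  n <- length(head) - 1
  r <- cor(cos(head[-1]), cos(head[-length(head)]))
  expect_lt(abs(r), 3 / sqrt(n))
})

test_that("an absorbing switch matrix keeps the chain in its start state", {
  cfg <- sim_config(switch_matrix = diag(2), start_state = 2, seed = 6)
  tr <- simulate_true_track(cfg, duration_days = 120)
  expect_true(all(tr$state == 2))
})

test_that("state occupancy matches the chain's stationary distribution", {
  # oracle: stationary distribution by eigen-decomposition
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  ev <- eigen(t(P))
  statn <- Re(ev$vectors[, 1]); statn <- statn / sum(statn)
  set.seed(7)
  s <- ridleyfaf:::simulate_states(50000, P, 1L)
  expect_lt(abs(mean(s == 1) - statn[1]), 0.02)
})

test_that("state dwell times are geometric with the configured mean", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  set.seed(8)
  s <- ridleyfaf:::simulate_states(50000, P, 1L)
  r <- rle(s)
  for (k in 1:2) {
    dwell <- r$lengths[r$values == k][-1]       # drop censored first run
    expect_equal(mean(dwell), 1 / (1 - P[k, k]), tolerance = 0.05)
  }
})

test_that("noise-free fixes coincide with the interpolated true path", {
  cfg <- sim_config(lc_error_scale_km = c(`3` = 0, `2` = 0, `1` = 0,
                                          `0` = 0, A = 0, B = 0),
                    z_fraction = 0, seed = 9)
  tr <- simulate_true_track(cfg, duration_days = 30)
  fx <- simulate_argos_fixes(tr, cfg)
  prj <- albers_projection()
  pt <- project_points(prj, tr$lon, tr$lat)
  pf <- project_points(prj, fx$lon, fx$lat)
  th <- as.numeric(fx$time) ; tt <- as.numeric(tr$time)
  ix <- approx(tt, pt$x, th)$y; iy <- approx(tt, pt$y, th)$y
  expect_lt(max(sqrt((pf$x - ix)^2 + (pf$y - iy)^2)), 1e-6)
})

test_that("the duty cycle gates fix times", {
  cfg <- sim_config(duty_cycle_hours = c(on = 6, off = 6), seed = 10)
  tr <- simulate_true_track(cfg, duration_days = 60)
  fx <- simulate_argos_fixes(tr, cfg)
  rel_h <- as.numeric(difftime(fx$time, tr$time[1], units = "hours"))
  expect_true(all((rel_h %% 12) < 6))
})

test_that("location-class frequencies match the configured probabilities", {
  probs <- c(`3` = 0.1, `2` = 0.1, `1` = 0.2, `0` = 0.2, A = 0.2, B = 0.2)
  cfg <- sim_config(lc_probs = probs, z_fraction = 0,
                    fix_rate_per_hour = 2, duty_cycle_hours = c(6, 0),
                    seed = 11)
  tr <- simulate_true_track(cfg, duration_days = 240)
  fx <- simulate_argos_fixes(tr, cfg)
  expect_gt(nrow(fx), 10000)
  freq <- table(factor(fx$lc, names(probs))) / nrow(fx)
  expect_true(all(abs(as.numeric(freq) - probs) < 0.02))
})

test_that("observation errors follow the configured t distribution by class", {
  cfg <- sim_config(lc_probs = c(`3` = 0, `2` = 0, `1` = 0, `0` = 0,
                                 A = 1, B = 0),
                    lc_error_scale_km = c(`3` = 0.25, `2` = 0.5, `1` = 1.5,
                                          `0` = 5, A = 8, B = 15),
                    z_fraction = 0, fix_rate_per_hour = 1.2,
                    duty_cycle_hours = c(6, 0), seed = 12)
  tr <- simulate_true_track(cfg, duration_days = 240)
  fx <- simulate_argos_fixes(tr, cfg)
  prj <- albers_projection()
  pt <- project_points(prj, tr$lon, tr$lat)
  pf <- project_points(prj, fx$lon, fx$lat)
  th <- as.numeric(fx$time); tt <- as.numeric(tr$time)
  errx <- (pf$x - approx(tt, pt$x, th)$y) / 8
  expect_gt(length(errx), 5000)
  ks <- suppressWarnings(ks.test(errx, "pt", df = 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("tracks and fixes are reproducible from the seed", {
  cfg <- sim_config(seed = 13)
  t1 <- simulate_true_track(cfg, duration_days = 50)
  t2 <- simulate_true_track(cfg, duration_days = 50)
  expect_identical(t1, t2)
  f1 <- simulate_argos_fixes(t1, cfg)
  f2 <- simulate_argos_fixes(t2, cfg)
  expect_identical(f1, f2)
  cfg2 <- sim_config(seed = 14)
  t3 <- simulate_true_track(cfg2, duration_days = 50)
  expect_false(identical(t1$lon, t3$lon))
})

test_that("land avoidance keeps simulated tracks at sea", {
  env <- test_env()
  cfg <- sim_config(seed = 15)
  tr <- simulate_true_track(cfg, env = env, duration_days = 150)
  b <- env_extract(env, "bathy", tr$lon, tr$lat)
  expect_true(all(b < 0, na.rm = TRUE))
})

test_that("environmental fields are deterministic in the seed and coherent", {
  e1 <- generate_environment(lon_range = c(-94, -91), lat_range = c(26.5, 29.9),
                             seed = 42)
  e2 <- generate_environment(lon_range = c(-94, -91), lat_range = c(26.5, 29.9),
                             seed = 42)
  expect_identical(e1$bathy, e2$bathy)
  expect_identical(e1$sst, e2$sst)
  e3 <- generate_environment(lon_range = c(-94, -91), lat_range = c(26.5, 29.9),
                             seed = 43)
  expect_false(identical(e1$bathy, e3$bathy))
  expect_error(generate_environment(lon_range = c(-94, -94)), "degenerate")
  # coastline boundary condition: elevation crosses zero at the coast curve
  env <- test_env()
  mid <- env$coast[seq(50, nrow(env$coast) - 50, by = 40), ]
  b <- env_extract(env, "bathy", mid$lon, mid$lat)
  expect_true(all(abs(b) < 2.5))
  # land cells above water, SST plausible
  expect_true(all(env$sst > 20 & env$sst < 30))
  # mainland distance non-negative, zero inside
  d <- distance_to_polygon_km(env$mainland$lon[5], env$mainland$lat[5] + 0.3,
                              env$mainland, env$proj)
  expect_equal(d, 0)
})

test_that("raster and polygon round-trips through disk preserve values", {
  env <- test_env()
  tmp <- tempfile(fileext = ".asc")
  write_ascii_grid(env, "sst", tmp)
  back <- read_ascii_grid(tmp)
  expect_equal(back$lon, env$lon, tolerance = 1e-9)
  expect_equal(back$values, env$sst, tolerance = 1e-6,
               ignore_attr = TRUE)
  gj <- tempfile(fileext = ".geojson")
  write_geojson_polygons(env$islands, gj)
  polys <- read_geojson_polygons(gj)
  expect_length(polys, 1)
  want <- env$islands[[1]]$lon          # writer closes the ring if needed
  expect_equal(polys[[1]]$lon[seq_along(want)], want, tolerance = 1e-7)
})
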