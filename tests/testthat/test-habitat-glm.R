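# a 500 x 250 km planar window inside the flat_env raster footprint
shelf_bbox <- c(-400, 100, 50, 300)

test_that("the lattice covers a fully-qualifying shelf exactly", {
  env <- flat_env(depth = -50)
  g <- build_grid(env, bbox = shelf_bbox)
  expect_equal(nrow(g), 20 * 10)
  expect_equal(sort(unique(diff(sort(unique(g$x))))), 25)
  expect_equal(sort(unique(diff(sort(unique(g$y))))), 25)
})

test_that("cells wholly outside the isobath band are excluded", {
  deep <- flat_env(depth = -200)
  expect_error(build_grid(deep, bbox = shelf_bbox), "no grid cells")
  # half the domain in-band: bathymetry varies with longitude
  env <- flat_env(depth = -50)
  nl <- length(env$lon)
  env$bathy[seq_len(floor(nl / 2)), ] <- -200
  g_all <- build_grid(flat_env(depth = -50))
  g_half <- build_grid(env)
  # roughly the western half drops out (edge cells may straddle the divide)
  expect_lt(nrow(g_half), 0.6 * nrow(g_all))
  expect_gt(nrow(g_half), 0.35 * nrow(g_all))
})

test_that("foraging-day counts pool turtles and drop brief periods", {
  env <- flat_env(depth = -50)
  g <- build_grid(env, bbox = shelf_bbox)
  # cell centers of two known cells
  a <- g[g$x == shelf_bbox[1] + 12.5 & g$y == shelf_bbox[3] + 12.5, ]
  b <- g[g$x == shelf_bbox[1] + 37.5 & g$y == shelf_bbox[3] + 12.5, ]
  lla <- unproject_points(env$proj, a$x, a$y)
  llb <- unproject_points(env$proj, b$x, b$y)
  daily <- data.frame(lon = c(rep(lla$lon, 3), llb$lon),
                      lat = c(rep(lla$lat, 3), llb$lat),
                      period_days = c(3, 3, 3, 1))
  counts <- count_foraging_days(daily, g, env$proj)
  expect_equal(counts$days[counts$cell == a$cell], 3L)
  expect_equal(counts$days[counts$cell == b$cell], 0L)     # < 2-day period
  # pooling two animals in one cell
  daily2 <- data.frame(lon = rep(lla$lon, 10), lat = rep(lla$lat, 10),
                       period_days = 5)
  counts2 <- count_foraging_days(daily2, g, env$proj)
  expect_equal(counts2$days[counts2$cell == a$cell], 10L)
  # conservation: totals equal qualifying in-grid locations
  set.seed(71)
  ll <- unproject_points(env$proj, runif(300, shelf_bbox[1], shelf_bbox[2]),
                         runif(300, shelf_bbox[3], shelf_bbox[4]))
  daily3 <- data.frame(lon = ll$lon, lat = ll$lat,
                       period_days = sample(c(1, 5), 300, replace = TRUE))
  counts3 <- count_foraging_days(daily3, g, env$proj)
  expect_equal(sum(counts3$days), sum(daily3$period_days >= 2))
})

test_that("cell subsampling is exact, seeded, and validated", {
  g <- data.frame(cell = 1:778, x = runif(778))
  s <- subsample_cells(g, 0.2, seed = 72)
  expect_equal(nrow(s), 155)                       # floor(0.2 * 778)
  expect_identical(s, subsample_cells(g, 0.2, seed = 72))
  expect_false(identical(s$cell, subsample_cells(g, 0.2, seed = 73)$cell))
  expect_equal(nrow(subsample_cells(g, 1)), 778)
  expect_error(subsample_cells(g, 0), "fraction")
  expect_error(subsample_cells(g, 1.2), "fraction")
})

test_that("a covariate-free response yields null slopes and log-mean intercept", {
  set.seed(73)
  n <- 200
  cells <- data.frame(dist_release_km = rnorm(n, 800, 300),
                      dist_mainland_km = rnorm(n, 30, 20),
                      sst_c = rnorm(n, 25, 1),
                      bathy_m = rnorm(n, -20, 10),
                      npp = rnorm(n, 3600, 1000),
                      days = rpois(n, 12))
  fit <- fit_log_glm(cells)
  tb <- fit$table
  slopes <- tb[tb$parameter != "(Intercept)", ]
  expect_true(all(abs(slopes$estimate) < 2.5 * slopes$se))
  ic <- tb[tb$parameter == "(Intercept)", ]
  expect_equal(ic$estimate, log(mean(cells$days)), tolerance = 0.5)
})

test_that("rescaling a covariate's units rescales its coefficient inversely", {
  set.seed(74)
  n <- 155
  cells <- data.frame(dist_release_km = rnorm(n, 800, 300),
                      dist_mainland_km = rnorm(n, 30, 20),
                      sst_c = rnorm(n, 25, 1),
                      bathy_m = rnorm(n, -20, 10),
                      npp = rnorm(n, 3600, 1000))
  cells$days <- rpois(n, exp(2 + 0.01 * cells$dist_mainland_km -
                               0.3 * (cells$sst_c - 25)))
  f1 <- fit_log_glm(cells)
  cells2 <- cells; cells2$dist_mainland_km <- 2 * cells2$dist_mainland_km
  f2 <- fit_log_glm(cells2)
  b1 <- f1$table$estimate[f1$table$parameter == "dist_mainland_km"]
  b2 <- f2$table$estimate[f2$table$parameter == "dist_mainland_km"]
  expect_equal(b2, b1 / 2, tolerance = 1e-8)
})

test_that("published-coefficient simulations are recovered within 2 SE", {
  r <- glm_recovery_experiment(seed = 2, n_replicates = 15)
  expect_gte(r$min_pct_within_2se, 80)
  expect_equal(unname(r$mean_estimates["sst_c"]), -0.8138, tolerance = 0.05)
  # consistency: per-replicate estimation error shrinks as cells grow 10x
  r_big <- glm_recovery_experiment(seed = 2, n_replicates = 15, n_cells = 1550)
  expect_true(all(r_big$rmse_relative < r$rmse_relative))
})

test_that("regression inputs are validated", {
  small <- data.frame(days = 1:5, dist_release_km = 1:5,
                      dist_mainland_km = 1:5, sst_c = 1:5, bathy_m = 1:5,
                      npp = 1:5)
  expect_error(fit_log_glm(small), "at least 20")
  bad <- small[rep(1:5, 10), ]
  bad$npp[3] <- Inf
  expect_error(fit_log_glm(bad), "non-finite")
})
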