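test_that("reading splits animals, sorts, and keeps the better duplicate LC", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("turtle_id,utc_timestamp,lon,lat,lc",
               "a,2010-06-01T06:00:00,-92.0,27.0,B",
               "a,2010-06-01T00:00:00,-92.1,27.1,1",
               "a,2010-06-01T06:00:00,-92.5,27.5,2",
               "b,2010-06-02T00:00:00,-91.0,26.0,0",
               "a,2010-06-01T12:00:00,-92.2,27.0,Z"), f)
  trks <- read_argos_table(f)
  expect_named(trks, c("a", "b"))
  expect_equal(nrow(trks$a), 3)
  expect_equal(nrow(trks$b), 1)
  dup <- trks$a[trks$a$time == as.POSIXct("2010-06-01 06:00:00", tz = "UTC"), ]
  expect_equal(dup$lc, "2")                 # 2 beats B at the tied timestamp
  expect_equal(dup$lon, -92.5)
  # class-Z fixes are parsed and retained for the downstream filter
  expect_true("Z" %in% trks$a$lc)
  filtered <- filter_fixes(trks$a)
  expect_false("Z" %in% filtered$lc)
})

test_that("unparseable rows are dropped with a warning; empty file warns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("turtle_id,utc_timestamp,lon,lat,lc",
               "a,2010-06-01T00:00:00,-92.0,27.0,3",
               "a,not-a-time,-92.0,27.0,3",
               "a,2010-06-02T00:00:00,-999,27.0,Q"), f)
  expect_warning(trks <- read_argos_table(f), "unparseable")
  expect_equal(nrow(trks$a), 1)
  f2 <- tempfile(fileext = ".csv")
  writeLines("turtle_id,utc_timestamp,lon,lat,lc", f2)
  expect_warning(out <- read_argos_table(f2), "empty")
  expect_length(out, 0)
})

test_that("track writing round-trips through read_argos_table", {
  cfg <- sim_config(seed = 21)
  tr <- simulate_true_track(cfg, duration_days = 20)
  fx <- simulate_argos_fixes(tr, cfg)
  f <- tempfile(fileext = ".csv")
  write_tracks(fx, f)
  back <- read_argos_table(f)[[1]]
  expect_equal(nrow(back), length(unique(fx$time)))
  expect_equal(back$lon, fx$lon[!duplicated(fx$time)], tolerance = 1e-6)
  expect_true("true_state" %in% names(back))
})

test_that("depth filtering applies only in foraging context; land always", {
  env <- flat_env(depth = -150)
  tr <- make_track(lon = c(-92, -92.1, -92.2), lat = c(26, 26.05, 26.1))
  # deep water: removed when foraging, retained during migration context
  expect_equal(nrow(filter_fixes(tr, env, mode_context = "foraging")), 0)
  expect_equal(nrow(filter_fixes(tr, env, mode_context = "any")), 3)
  # on land (positive elevation): always removed
  land_env <- flat_env(depth = 5)
  expect_equal(nrow(filter_fixes(tr, land_env, mode_context = "any")), 0)
})

test_that("the speed filter drops spatially distant fixes and is idempotent", {
  # third fix requires ~ 111 km in one hour
  tr <- make_track(lon = c(-92, -92.02, -93.2, -92.04),
                   lat = rep(26, 4), dt_hours = 1)
  out <- filter_fixes(tr)
  expect_equal(out$lon, c(-92, -92.02, -92.04))
  again <- filter_fixes(out)
  expect_equal(out[, c("lon", "lat")], again[, c("lon", "lat")])
  env <- test_env()
  cfg <- sim_config(seed = 22)
  sim <- simulate_argos_fixes(simulate_true_track(cfg, env = env,
                                                  duration_days = 60), cfg)
  once <- suppressWarnings(filter_fixes(sim, env))
  twice <- suppressWarnings(filter_fixes(once, env))
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$lon, twice$lon)
})

test_that("mean daily locations average per UTC day", {
  tr <- make_track(lon = c(1, 2, 3, 5), lat = c(10, 10, 10, 11),
                   t0 = as.POSIXct("2010-06-01 01:00:00", tz = "UTC"),
                   dt_hours = 8)
  md <- mean_daily_locations(tr)
  expect_equal(nrow(md), 2)                  # 3 fixes day 1, 1 fix day 2
  expect_equal(md$lon[1], 2)                 # arithmetic mean of 1,2,3
  expect_equal(md$n_fixes, c(3L, 1L))
  expect_equal(nrow(mean_daily_locations(tr[0, ])), 0)
  # output count never exceeds the number of distinct fix dates
  cfg <- sim_config(seed = 23)
  fx <- simulate_argos_fixes(simulate_true_track(cfg, duration_days = 25), cfg)
  md2 <- mean_daily_locations(fx)
  expect_lte(nrow(md2), length(unique(as.Date(fx$time, tz = "UTC"))))
  expect_lte(nrow(md2), 26)
})

test_that("total path distance dominates the straight-line distance", {
  two <- make_track(lon = c(-92, -91), lat = c(26, 26.5))
  d <- travel_distances(two)
  expect_equal(d[["total_path_km"]], d[["straight_line_km"]])
  # collinear equal legs along a meridian add exactly
  tri <- make_track(lon = rep(-92, 3), lat = c(26, 26.5, 27))
  d2 <- travel_distances(tri)
  expect_equal(d2[["total_path_km"]],
               2 * great_circle_km(-92, 26, -92, 26.5), tolerance = 1e-9)
  expect_error(travel_distances(two[1, ]), "fewer than 2")
  set.seed(24)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    tr <- make_track(lon = runif(n, -95, -90), lat = runif(n, 24, 29))
    d <- travel_distances(tr)
    expect_gte(d[["total_path_km"]], d[["straight_line_km"]] - 1e-9)
  }
})
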