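test_that("haversine distance matches the closed form and is symmetric", {
  expect_equal(great_circle_km(-90, 25, -90, 25), 0)
  # one degree of longitude on the equator: 6371 * pi / 180
  expect_equal(great_circle_km(0, 0, 1, 0), 6371 * pi / 180, tolerance = 1e-6)
  set.seed(1)
  lon <- runif(100, -98, -80); lat <- runif(100, 20, 31)
  lon2 <- runif(100, -98, -80); lat2 <- runif(100, 20, 31)
  expect_equal(great_circle_km(lon, lat, lon2, lat2),
               great_circle_km(lon2, lat2, lon, lat))
})

test_that("Albers projection round-trips to sub-meter accuracy", {
  prj <- albers_projection()
  set.seed(2)
  lon <- runif(1000, -98, -81); lat <- runif(1000, 18, 31)
  xy <- project_points(prj, lon, lat)
  back <- unproject_points(prj, xy$x, xy$y)
  err_km <- great_circle_km(lon, lat, back$lon, back$lat)
  expect_lt(max(err_km), 1e-3)                       # < 1 m
  ctr <- project_points(prj, -90, 25)
  expect_equal(unname(unlist(ctr)), c(0, 0), tolerance = 1e-9)
})

test_that("planar distances agree with great-circle at local scale", {
  prj <- albers_projection()
  set.seed(3)
  lon <- runif(200, -94, -90); lat <- runif(200, 24, 28)
  lon2 <- lon + runif(200, -0.5, 0.5); lat2 <- lat + runif(200, -0.5, 0.5)
  p1 <- project_points(prj, lon, lat); p2 <- project_points(prj, lon2, lat2)
  dpl <- sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2)
  dgc <- great_circle_km(lon, lat, lon2, lat2)
  keep <- dgc < 100 & dgc > 0.1
  expect_true(all(abs(dpl[keep] - dgc[keep]) / dgc[keep] < 0.005))
})

test_that("projection preserves areas across the domain", {
  prj <- albers_projection()
  for (ll in list(c(-96, 22), c(-90, 27), c(-84, 30))) {
    # 0.5-degree square; spherical area is R^2 * dlam * d(sin phi)
    lon <- ll[1] + c(0, 0.5, 0.5, 0); lat <- ll[2] + c(0, 0, 0.5, 0.5)
    xy <- project_points(prj, lon, lat)
    planar <- polygon_area_centroid(xy$x, xy$y)$area
    sph <- 6371^2 * (0.5 * pi / 180) *
      (sin((ll[2] + 0.5) * pi / 180) - sin(ll[2] * pi / 180))
    expect_lt(abs(planar - sph) / sph, 0.001)
  }
})

test_that("point-to-polygon distance handles inside, offset, and islands", {
  prj <- albers_projection()
  # synthetic straight coast segment along a parallel; a point 10 km due
  # south of it in the projected plane must be 10.0 km away
  coast <- list(lon = seq(-91, -89, by = 0.01),
                lat = rep(27, 201))
  coast$lon <- c(coast$lon, rev(coast$lon))
  coast$lat <- c(coast$lat, rep(28, 201))
  base <- project_points(prj, -90, 27)
  pt <- unproject_points(prj, base$x, base$y - 10)
  d <- distance_to_polygon_km(pt$lon, pt$lat, coast, prj)
  expect_equal(d, 10, tolerance = 0.01)
  inside <- distance_to_polygon_km(-90, 27.5, coast, prj)
  expect_equal(inside, 0)
  # nearest land (mainland + island) can only be closer than the mainland
  env <- test_env()
  set.seed(4)
  lon <- runif(20, -93.8, -91.2); lat <- runif(20, 26.6, 28.3)
  dm <- distance_to_polygon_km(lon, lat, env$mainland, env$proj)
  dl <- distance_to_polygons_km(lon, lat, c(list(env$mainland), env$islands),
                                env$proj)
  expect_true(all(dl <= dm + 1e-9))
})

test_that("point_in_polygon applies the even-odd rule", {
  sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_true(point_in_polygon(0.5, 0.5, sq$x, sq$y))
  expect_false(point_in_polygon(1.5, 0.5, sq$x, sq$y))
  expect_false(point_in_polygon(-0.1, -0.1, sq$x, sq$y))
})
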