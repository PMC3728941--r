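test_that("LSCV bandwidth lands near the reference rule for Gaussian data", {
  set.seed(51)
  pts <- cbind(rnorm(500), rnorm(500))
  bw <- lscv_bandwidth(pts)
  href <- 1.06 * 500^(-1 / 5)
  expect_gt(bw$h[1], 0.5 * href)
  expect_lt(bw$h[1], 2 * href)
  expect_false(bw$rescaled)
  expect_error(lscv_bandwidth(pts[1:5, ]), "at least 10")
  expect_error(lscv_bandwidth(matrix(1, 20, 2)), "degenerate")
})

test_that("the estimator agrees with the brute-force CV score on duplicated data", {
  set.seed(52)
  pts <- cbind(rnorm(150), rnorm(150))
  dup <- rbind(pts, pts)
  res <- suppressWarnings(lscv_bandwidth(dup))
  h2 <- res$h_factor
  # independent oracle: recompute the duplicated-data CV score on a dense grid
  n <- nrow(dup)
  sdx <- sd(dup[, 1]); sdy <- sd(dup[, 2])
  scale <- rep(sqrt((sdx^2 + sdy^2) / 2), 2)
  z <- sweep(dup, 2, scale, "/")
  d2 <- as.matrix(dist(z))^2
  off <- d2[upper.tri(d2)]
  cv <- function(h) {
    (n + 2 * sum(exp(-off / (4 * h^2)))) / (n^2 * 4 * pi * h^2) -
      4 * sum(exp(-off / (2 * h^2))) / (n * (n - 1) * 2 * pi * h^2)
  }
  # duplicates make the score diverge as h -> 0: the oracle is the best
  # interior local minimum if one exists, else the documented fallback to
  # the reference bandwidth must have fired
  href <- 1.06 * n^(-1 / 5)
  hs <- href * exp(seq(log(0.05), log(3), length.out = 300))
  sc <- vapply(hs, cv, numeric(1))
  interior <- which(diff(sign(diff(sc))) > 0) + 1
  if (length(interior) > 0) {
    h_oracle <- hs[interior[which.min(sc[interior])]]
    expect_false(res$fallback)
    expect_equal(h2, h_oracle, tolerance = 0.1)
  } else {
    expect_true(res$fallback)
    expect_equal(h2, href, tolerance = 1e-8)
    expect_warning(lscv_bandwidth(dup), "no interior minimum")
  }
  # either way the returned bandwidth stays at the unduplicated scale
  h1 <- lscv_bandwidth(pts)$h_factor
  expect_gt(h2, 0.4 * h1)
  expect_lt(h2, 2.5 * h1)
})

test_that("anisotropic clouds trigger rescaling with per-axis bandwidths", {
  set.seed(53)
  pts <- cbind(rnorm(300, sd = 10), rnorm(300, sd = 1))
  bw <- lscv_bandwidth(pts)
  expect_true(bw$rescaled)
  ratio <- bw$h[1] / bw$h[2]
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("the density grid integrates to one and matches kde2d", {
  skip_if_not_installed("MASS")
  set.seed(54)
  pts <- cbind(rnorm(200), rnorm(200, sd = 2))
  h <- c(0.5, 0.8)
  g <- ridleyfaf:::kde_evaluate(pts, h)
  expect_equal(sum(g$z) * g$cell^2, 1, tolerance = 0.005)
  # cross-check values against MASS::kde2d (its h is 4x the kernel sd)
  m <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h, n = 25,
                   lims = c(-2, 2, -3, 3))
  ours <- ridleyfaf:::kde_evaluate(pts, h, gx = m$x, gy = m$y)
  expect_equal(ours$z, m$z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("core-area mass, nesting, and water clipping behave", {
  set.seed(55)
  pts <- cbind(rnorm(400), rnorm(400))
  bw <- lscv_bandwidth(pts)
  core50 <- kde_core_area(pts, bw$h, probability = 0.5)
  expect_equal(core50$mass_in, 0.5, tolerance = 0.01)
  core95 <- kde_core_area(pts, bw$h, probability = 0.95)
  expect_lt(core50$area_km2, core95$area_km2)
  land <- kde_core_area(pts, bw$h, water_fn = function(x, y) rep(FALSE, length(x)))
  expect_equal(land$area_km2, 0)
  expect_equal(land$area_unclipped_km2, core50$area_km2)
})

test_that("areas scale quadratically with coordinate scale", {
  set.seed(56)
  pts <- cbind(rnorm(400), rnorm(400))
  bw <- lscv_bandwidth(pts)
  a1 <- kde_core_area(pts, bw$h)$area_km2
  a2 <- kde_core_area(2 * pts, 2 * bw$h)$area_km2
  expect_equal(a2 / a1, 4, tolerance = 0.05)
})

test_that("the centroid comes from the largest activity center", {
  set.seed(57)
  # two well-separated clusters with point mass 3:1
  pts <- rbind(cbind(rnorm(300, 0, 1), rnorm(300, 0, 1)),
               cbind(rnorm(100, 30, 1), rnorm(100, 30, 1)))
  core <- kde_core_area(pts, c(1, 1))
  expect_gte(nrow(core$centers), 2)
  cen <- largest_center_centroid(core)
  expect_equal(unname(cen), c(0, 0), tolerance = 0.5)
  # translation equivariance
  core2 <- kde_core_area(sweep(pts, 2, c(100, -50), "+"), c(1, 1))
  cen2 <- largest_center_centroid(core2)
  expect_equal(unname(cen2), unname(cen) + c(100, -50), tolerance = 0.05)
  # single symmetric cloud: centroid at its center
  core3 <- kde_core_area(cbind(rnorm(500, 5), rnorm(500, -3)), c(0.4, 0.4))
  expect_equal(unname(largest_center_centroid(core3)), c(5, -3),
               tolerance = 0.3)
})
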