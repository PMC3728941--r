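test_that("the estimation grid has exact spacing and in-range offsets", {
  tr <- make_track(lon = seq(-92, -91, length.out = 31), lat = rep(26, 31),
                   dt_hours = 8)                       # exactly 10 days
  g <- build_time_grid(tr, 8)
  expect_length(g$times, 31)                           # 30 intervals
  expect_equal(unique(diff(as.numeric(g$times))), 8 * 3600)
  expect_equal(g$frac[1], 0)                           # fix on a node
  expect_error(build_time_grid(tr[1:2, ], 8), "too short")
  set.seed(31)
  tr2 <- make_track(lon = rep(-92, 500), lat = rep(26, 500))
  tr2$time <- tr2$time[1] + sort(runif(500, 0, 200 * 3600))
  g2 <- build_time_grid(tr2, 8)
  expect_true(all(g2$frac >= 0 & g2$frac <= 1))
  expect_true(all(g2$interval >= 0 &
                    g2$interval <= length(g2$times) - 2))
})

test_that("mode classification is a monotone threshold on b_mean", {
  path <- data.frame(b_mean = c(2, 2, 2))
  expect_equal(classify_modes(path), rep("foraging", 3))
  path$b_mean <- c(1, 1, 1)
  expect_equal(classify_modes(path), rep("migration", 3))
  set.seed(32)
  path <- data.frame(b_mean = runif(200, 1, 2))
  n_for <- sapply(c(1.2, 1.5, 1.8), function(ct)
    sum(classify_modes(path, ct) == "foraging"))
  expect_true(all(diff(n_for) <= 0))
})

test_that("convergence diagnostics separate mixed from shifted chains", {
  set.seed(33)
  a <- matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("p1", "p2")))
  d <- check_convergence(list(a, a))
  expect_true(all(abs(d$psrf - 1) < 0.01))
  b <- a; b[, 1] <- b[, 1] + 3                       # different stationary mean
  d2 <- check_convergence(list(a, b))
  expect_gt(d2$psrf[1], 1.1)
  expect_true(d2$flag[1])
  # i.i.d. chains: effective sample size near the actual sample count
  c1 <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "p"))
  c2 <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "p"))
  d3 <- check_convergence(list(c1, c2))
  expect_equal(d3$ess, 4000, tolerance = 0.2)
  expect_error(check_convergence(list(a)), "two chains")
})

test_that("a single-state persistent walk is recovered from clean fixes", {
  cfg <- sim_config(gamma_migration = 0.8, gamma_foraging = 0.2,
                    turn_concentration = c(1, 1), process_sd_km = c(3, 3),
                    switch_matrix = diag(2), start_state = 1,
                    lc_probs = c(`3` = 1, `2` = 0, `1` = 0, `0` = 0,
                                 A = 0, B = 0),
                    lc_error_scale_km = c(`3` = 0.01, `2` = 0.5, `1` = 1.5,
                                          `0` = 5, A = 8, B = 15),
                    duty_cycle_hours = c(6, 0), fix_rate_per_hour = 1,
                    z_fraction = 0, seed = 34)
  tr <- simulate_true_track(cfg, duration_days = 120)
  fx <- simulate_argos_fixes(tr, cfg)
  fit <- suppressWarnings(
    fit_switching_dcrw(fx, ssm_config(n_iterations = 2000, burn_in = 1000,
                                      thin = 2, seed = 35)))
  g1 <- fit$params$mean[fit$params$parameter == "gamma1"]
  expect_equal(g1, 0.8, tolerance = 0.1)
  # with near-noise-free fixes the posterior path sits on the fixes
  prj <- albers_projection()
  pf <- project_points(prj, fx$lon, fx$lat)
  px <- approx(as.numeric(fit$path$time), fit$path$x, as.numeric(fx$time))$y
  py <- approx(as.numeric(fit$path$time), fit$path$y, as.numeric(fx$time))$y
  expect_lt(stats::quantile(sqrt((pf$x - px)^2 + (pf$y - py)^2), 0.95), 1)
})

test_that("well-separated behavioural states are recovered and classified", {
  r <- suppressWarnings(ssm_recovery_experiment(seed = 3, duration_days = 100,
                                                n_iterations = 1000,
                                                burn_in = 800, thin = 1))
  expect_lt(abs(r$gamma_migration - 0.8), 0.15)
  expect_lt(abs(r$gamma_foraging - 0.2), 0.15)
  expect_gt(r$pct_nodes_correct, 85)
  # label identifiability: state 1 is always the higher-persistence state
  for (ch in r$fit$chains)
    expect_true(all(ch[, "gamma1"] > ch[, "gamma2"]))
})

test_that("credible intervals cover the generating persistence values", {
  hits <- c(gamma1 = 0, gamma2 = 0)
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(gamma_migration = 0.8, gamma_foraging = 0.2,
                      mean_turn = c(0, pi), turn_concentration = c(1, 1),
                      process_sd_km = c(3, 3),
                      switch_matrix = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                             byrow = TRUE),
                      lc_probs = c(`3` = 0.4, `2` = 0.3, `1` = 0.3, `0` = 0,
                                   A = 0, B = 0),
                      z_fraction = 0, seed = 4000 + r)
    tr <- simulate_true_track(cfg, duration_days = 80)
    fx <- simulate_argos_fixes(tr, cfg)
    fit <- suppressWarnings(
      fit_switching_dcrw(fx, ssm_config(n_iterations = 800, burn_in = 600,
                                        thin = 1, seed = 5000 + r)))
    p <- fit$params
    truth <- c(gamma1 = 0.8, gamma2 = 0.2)
    for (nm in names(truth)) {
      row <- p[p$parameter == nm, ]
      if (truth[nm] >= row$q2.5 && truth[nm] <= row$q97.5)
        hits[nm] <- hits[nm] + 1
    }
  }
  expect_gte(hits[["gamma1"]], 18)
  expect_gte(hits[["gamma2"]], 18)
})

test_that("class-Z fixes are refused into the fit and the fit is seeded", {
  cfg <- sim_config(seed = 36, z_fraction = 0.1)
  tr <- simulate_true_track(cfg, duration_days = 40)
  fx <- simulate_argos_fixes(tr, cfg)
  expect_true(any(fx$lc == "Z"))
  sc <- ssm_config(n_iterations = 100, burn_in = 100, thin = 1, seed = 37)
  expect_warning(f1 <- fit_switching_dcrw(fx, sc), "class-Z")
  f2 <- suppressWarnings(fit_switching_dcrw(fx, sc))
  expect_identical(f1$path$b_mean, f2$path$b_mean)
})
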