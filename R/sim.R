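#' Configuration for the synthetic track generator
#'
#' Collects the parameters of the two-state switching correlated random walk
#' used to generate ground-truthed tracks, and of the Argos-like observation
#' process layered on top of them. Defaults describe a postnesting cohort:
#' 31 turtles tracked 98-342 days, moving on an 8-h step with a persistent
#' migration state and a localised foraging state, observed through a
#' 6 h on / 6 h off duty cycle with location-class-dependent heavy-tailed
#' errors.
#'
#' @param n_turtles number of animals in a simulated cohort.
#' @param duration_range days tracked per animal; each animal draws uniformly
#'   from this range unless `duration_days` is passed to the track simulator.
#' @param step_hours true-process step (h); matches the state-space model grid.
#' @param gamma_migration,gamma_foraging move persistence in [0,1] per state;
#'   migration must exceed foraging for the states to be identifiable.
#' @param mean_turn per-state mean turn angle (radians); the foraging default
#'   of pi (step reversal) is the area-restricted-search signature.
#' @param max_depth_m depth bound (positive metres) of the simulated habitat:
#'   steps into deeper water are redrawn, confining animals to the shelf as
#'   observed for this nearshore benthic forager.
#' @param turn_concentration per-state wrapped-Cauchy concentration in [0,1]
#'   of the step-to-step rotation (1 = deterministic mean turn).
#' @param process_sd_km per-state, per-axis step noise (km).
#' @param switch_matrix 2x2 row-stochastic behaviour transition matrix
#'   (rows/cols ordered migration, foraging).
#' @param start_state initial behavioural state (1 = migration, 2 = foraging).
#' @param lc_probs probability of each Argos location class 3,2,1,0,A,B.
#' @param lc_error_scale_km per-class scale of the isotropic t-distributed
#'   observation error.
#' @param lc_error_df per-class t degrees of freedom.
#' @param duty_cycle_hours c(on, off) transmitter schedule; off = 0 means
#'   continuous transmission.
#' @param fix_rate_per_hour mean Argos fix rate while the transmitter is on.
#' @param z_fraction fraction of fixes degraded to invalid class Z with
#'   `z_error_scale_km` error.
#' @param z_error_scale_km error scale of injected class-Z junk fixes.
#' @param seed integer seed; every simulator call derives its stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_turtles = 31,
                       duration_range = c(98, 342),
                       step_hours = 8,
                       gamma_migration = 0.8,
                       gamma_foraging = 0.2,
                       mean_turn = c(migration = 0, foraging = pi),
                       turn_concentration = c(migration = 0.95, foraging = 0.5),
                       process_sd_km = c(migration = 4, foraging = 1.5),
                       max_depth_m = 90,
                       switch_matrix = matrix(c(0.985, 0.015, 0.005, 0.995),
                                              2, 2, byrow = TRUE),
                       start_state = 1,
                       lc_probs = c(`3` = 0.05, `2` = 0.08, `1` = 0.12,
                                    `0` = 0.15, A = 0.25, B = 0.35),
                       lc_error_scale_km = c(`3` = 0.25, `2` = 0.5, `1` = 1.5,
                                             `0` = 5, A = 8, B = 15),
                       lc_error_df = c(`3` = 4, `2` = 4, `1` = 4,
                                       `0` = 4, A = 4, B = 4),
                       duty_cycle_hours = c(on = 6, off = 6),
                       fix_rate_per_hour = 0.7,
                       z_fraction = 0.02,
                       z_error_scale_km = 50,
                       seed = NULL) {
  cfg <- list(n_turtles = n_turtles, duration_range = duration_range,
              step_hours = step_hours,
              gamma = c(gamma_migration, gamma_foraging),
              mean_turn = unname(mean_turn),
              turn_concentration = unname(turn_concentration),
              process_sd_km = unname(process_sd_km),
              max_depth_m = max_depth_m,
              switch_matrix = switch_matrix, start_state = start_state,
              lc_probs = lc_probs, lc_error_scale_km = lc_error_scale_km,
              lc_error_df = lc_error_df,
              duty_cycle_hours = unname(duty_cycle_hours),
              fix_rate_per_hour = fix_rate_per_hour,
              z_fraction = z_fraction, z_error_scale_km = z_error_scale_km,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_turtles < 1) stop("n_turtles must be >= 1")
  if (any(cfg$duration_range <= 0)) stop("durations must be positive")
  if (cfg$step_hours <= 0) stop("step_hours must be positive")
  if (any(cfg$gamma < 0 | cfg$gamma > 1)) stop("gamma values must lie in [0, 1]")
  if (cfg$gamma[1] <= cfg$gamma[2])
    stop("gamma_migration must exceed gamma_foraging for an identifiable simulation")
  if (any(abs(rowSums(cfg$switch_matrix) - 1) > 1e-12))
    stop("switch_matrix rows must sum to 1")
  if (any(cfg$switch_matrix < 0 | cfg$switch_matrix > 1))
    stop("switch_matrix entries must be probabilities")
  if (any(cfg$lc_probs < 0) || abs(sum(cfg$lc_probs) - 1) > 1e-8)
    stop("lc_probs must be a probability vector over classes 3,2,1,0,A,B")
  if (any(cfg$turn_concentration < 0 | cfg$turn_concentration > 1))
    stop("turn_concentration must lie in [0, 1]")
  if (any(cfg$process_sd_km < 0)) stop("process_sd_km must be non-negative")
  if (cfg$max_depth_m <= 0) stop("max_depth_m must be positive")
  if (any(cfg$duty_cycle_hours < 0) || cfg$duty_cycle_hours[1] <= 0)
    stop("duty cycle on-window must be positive")
  invisible(cfg)
}

# Simulate the behavioural Markov chain.
simulate_states <- function(n, switch_matrix, start_state) {
  s <- integer(n)
  s[1] <- start_state
  u <- stats::runif(n)
  for (t in 2:n) s[t] <- if (u[t] < switch_matrix[s[t - 1], 1]) 1L else 2L
  s
}

#' Simulate a ground-truthed two-state track
#'
#' First-difference correlated random walk: the displacement at step t is a
#' damped (`gamma`), rotated (wrapped-Cauchy turn) copy of the previous
#' displacement plus isotropic Gaussian noise, with the damping, turn
#' distribution and noise scale switching between migration and foraging
#' according to the configured Markov chain. When environmental fields are
#' supplied, steps landing on land (or outside the raster) are redrawn up to
#' 50 times and then reflected, keeping the track at sea.
#'
#' @param config a [sim_config()].
#' @param id turtle identifier (also offsets the per-animal seed).
#' @param env optional `env_fields` for land avoidance.
#' @param release optional c(lon, lat) release point; defaults to a nearshore
#'   point on the synthetic shelf (or -97, 27.5 without `env`).
#' @param duration_days optional fixed tracking duration.
#' @param start_time POSIXct UTC start of the track.
#' @return A data.frame of class `true_track` with columns `turtle_id`,
#'   `time`, `lon`, `lat`, `state` (1 = migration, 2 = foraging), and
#'   attributes `release` and `step_hours`.
#' @export
simulate_true_track <- function(config, id = 1, env = NULL, release = NULL,
                                duration_days = NULL,
                                start_time = as.POSIXct("2010-06-15 00:00:00",
                                                        tz = "UTC")) {
  validate_sim_config(config)
  proj <- if (!is.null(env)) env$proj else albers_projection()
  seed <- if (!is.null(config$seed)) config$seed + 7919L * (id %% 1000L) else NULL
  with_seed(seed, {
    dur <- duration_days %||%
      stats::runif(1, config$duration_range[1], config$duration_range[2])
    if (dur <= 0) stop("zero or negative duration")
    n <- max(3L, as.integer(round(dur * 24 / config$step_hours)))
    if (is.null(release)) {
      release <- if (!is.null(env)) {
        rl <- env$lon_range[1] + 0.12 * diff(env$lon_range)
        c(rl, stats::approx(env$coast$lon, env$coast$lat, rl)$y - 0.18)
      } else c(-97, 27.5)
    }
    s <- simulate_states(n, config$switch_matrix, config$start_state)
    p0 <- project_points(proj, release[1], release[2])
    xy <- matrix(0, n, 2)
    xy[1, ] <- c(p0$x, p0$y)
    ang0 <- stats::runif(1, 0, 2 * pi)
    d_prev <- config$process_sd_km[1] * c(cos(ang0), sin(ang0))
    at_sea <- function(x, y) {
      if (is.null(env)) return(TRUE)
      ll <- unproject_points(proj, x, y)
      b <- env_extract(env, "bathy", ll$lon, ll$lat)
      !is.na(b) && b < 0 && b >= -config$max_depth_m
    }
    for (t in 2:n) {
      k <- s[t]
      ok <- FALSE
      for (attempt in 1:50) {
        th <- rwrapcauchy(1, config$mean_turn[k], config$turn_concentration[k])
        rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        d <- config$gamma[k] * as.vector(rot %*% d_prev) +
          stats::rnorm(2, 0, config$process_sd_km[k])
        cand <- xy[t - 1, ] + d
        if (at_sea(cand[1], cand[2])) { ok <- TRUE; break }
      }
      if (!ok) {            # reflect: bounce back along the previous step
        d <- -d_prev
        cand <- xy[t - 1, ] + d
      }
      xy[t, ] <- cand
      d_prev <- d
    }
    ll <- unproject_points(proj, xy[, 1], xy[, 2])
    out <- data.frame(turtle_id = id,
                      time = start_time + (seq_len(n) - 1) * config$step_hours * 3600,
                      lon = ll$lon, lat = ll$lat, state = s)
    attr(out, "release") <- release
    attr(out, "step_hours") <- config$step_hours
    class(out) <- c("true_track", "data.frame")
    out
  })
}

#' Simulate Argos-like fixes from a true track
#'
#' Fix times arise as a Poisson process thinned by the transmitter duty cycle
#' (anchored at the track start). Each fix is the true position linearly
#' interpolated to the fix time plus isotropic t-distributed error with the
#' drawn location class's scale and df. A configurable fraction of fixes is
#' degraded to invalid class Z with large error.
#'
#' @param track a `true_track`.
#' @param config the [sim_config()] used to generate it.
#' @param proj projection used for interpolation geometry.
#' @return A data.frame with columns `turtle_id`, `time`, `lon`, `lat`, `lc`
#'   and `true_state`.
#' @export
simulate_argos_fixes <- function(track, config,
                                 proj = albers_projection()) {
  validate_sim_config(config)
  if (nrow(track) == 0) stop("empty track")
  id <- track$turtle_id[1]
  seed <- if (!is.null(config$seed)) config$seed + 7919L * (id %% 1000L) + 13L else NULL
  with_seed(seed, {
    t0 <- as.numeric(track$time[1])
    dur_h <- (as.numeric(track$time[nrow(track)]) - t0) / 3600
    n_ev <- stats::rpois(1, config$fix_rate_per_hour * dur_h)
    # a deployment transmission anchors the record at the release time
    th <- sort(c(0, stats::runif(n_ev, 0, dur_h)))
    on <- config$duty_cycle_hours[1]; off <- config$duty_cycle_hours[2]
    if (off > 0) th <- th[(th %% (on + off)) < on]
    if (length(th) == 0)
      return(data.frame(turtle_id = integer(0), time = as.POSIXct(character(0), tz = "UTC"),
                        lon = numeric(0), lat = numeric(0), lc = character(0),
                        true_state = integer(0)))
    pxy <- project_points(proj, track$lon, track$lat)
    tt <- (as.numeric(track$time) - t0) / 3600
    fx <- stats::approx(tt, pxy$x, th)$y
    fy <- stats::approx(tt, pxy$y, th)$y
    state <- track$state[pmin(findInterval(th, tt), nrow(track))]
    classes <- names(config$lc_probs)
    lc <- sample(classes, length(th), replace = TRUE, prob = config$lc_probs)
    scale <- config$lc_error_scale_km[lc]
    df <- config$lc_error_df[lc]
    if (config$z_fraction > 0) {
      z <- stats::runif(length(th)) < config$z_fraction
      lc[z] <- "Z"
      scale[z] <- config$z_error_scale_km
      df[z] <- 4
    }
    ox <- fx + scale * stats::rt(length(th), df)
    oy <- fy + scale * stats::rt(length(th), df)
    ll <- unproject_points(proj, ox, oy)
    data.frame(turtle_id = id,
               time = track$time[1] + th * 3600,
               lon = ll$lon, lat = ll$lat, lc = lc,
               true_state = state)
  })
}

#' Simulate a postnesting cohort with Argos observations
#'
#' Generates `n_turtles` ground-truthed tracks over the supplied environment,
#' released from two tagging areas in the configured proportion (emulating a
#' primary and a secondary nesting beach), and observes each through the
#' Argos error model.
#'
#' @param config a [sim_config()] (its `seed` drives everything).
#' @param env an `env_fields` object.
#' @param site_split proportion of animals released at the first tagging site.
#' @return list with `tracks` (list of `true_track`), `fixes` (list of fix
#'   data.frames) and `meta` (per-animal release site, position, duration).
#' @export
simulate_cohort <- function(config, env, site_split = 22 / 31) {
  validate_sim_config(config)
  sites <- with_seed(config$seed,
    sample(c("PAIS", "RN"), config$n_turtles, replace = TRUE,
           prob = c(site_split, 1 - site_split)))
  rel_lon <- ifelse(sites == "PAIS",
                    env$lon_range[1] + 0.10 * diff(env$lon_range),
                    env$lon_range[1] + 0.04 * diff(env$lon_range))
  tracks <- vector("list", config$n_turtles)
  fixes <- vector("list", config$n_turtles)
  meta <- data.frame(turtle_id = seq_len(config$n_turtles), site = sites,
                     release_lon = NA_real_, release_lat = NA_real_,
                     duration_days = NA_real_)
  for (i in seq_len(config$n_turtles)) {
    rl <- rel_lon[i]
    rlat <- stats::approx(env$coast$lon, env$coast$lat, rl)$y - 0.18
    tr <- simulate_true_track(config, id = i, env = env, release = c(rl, rlat))
    tracks[[i]] <- tr
    fixes[[i]] <- simulate_argos_fixes(tr, config, proj = env$proj)
    meta$release_lon[i] <- rl
    meta$release_lat[i] <- rlat
    meta$duration_days[i] <- as.numeric(difftime(tr$time[nrow(tr)], tr$time[1],
                                                 units = "days"))
  }
  list(tracks = tracks, fixes = fixes, meta = meta)
}
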