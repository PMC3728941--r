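#' Configuration for the switching state-space model fit
#'
#' Defaults mirror the pipeline's production MCMC settings: locations and
#' behaviour estimated every eight hours, two independent parallel chains,
#' 10,000 retained samples after a 7000-iteration burn-in, thinned by five.
#' A lighter preset (`ssm_config(preset = "desk")`) is provided for
#' development and simulation experiments: 2000 retained, burn-in 1000,
#' thinned by two.
#'
#' @param step_hours regular grid step in hours.
#' @param n_iterations retained posterior samples per chain.
#' @param burn_in discarded initial iterations per chain.
#' @param thin thinning interval.
#' @param n_chains number of independent chains (>= 2 for convergence checks).
#' @param obs_scale_km named per-LC observation t scale (km); classes 3..B.
#' @param obs_df named per-LC t degrees of freedom.
#' @param sigma_prior_sd half-normal prior scale (km) on the per-axis process
#'   standard deviations.
#' @param mode_cutoff posterior-mean behaviour cutoff for foraging (on [1,2]).
#' @param seed integer seed for the sampler.
#' @param preset "paper" (full settings) or "desk" (reduced, for experiments).
#' @return list of class `ssm_config`.
#' @export
ssm_config <- function(step_hours = 8,
                       n_iterations = 10000, burn_in = 7000, thin = 5,
                       n_chains = 2,
                       obs_scale_km = c(`3` = 0.25, `2` = 0.5, `1` = 1.5,
                                        `0` = 5, A = 8, B = 15),
                       obs_df = c(`3` = 4, `2` = 4, `1` = 4,
                                  `0` = 4, A = 4, B = 4),
                       sigma_prior_sd = 10,
                       mode_cutoff = 1.5,
                       seed = NULL,
                       preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk" && missing(n_iterations)) {
    n_iterations <- 2000; burn_in <- 1000; thin <- 2
  }
  if (n_iterations < 1 || burn_in < 0 || thin < 1 || step_hours <= 0)
    stop("iteration counts and step must be positive; thin >= 1")
  if (n_chains < 2)
    warning("n_chains < 2: convergence diagnostics will be unavailable")
  structure(list(step_hours = step_hours, n_iterations = n_iterations,
                 burn_in = burn_in, thin = thin, n_chains = n_chains,
                 obs_scale_km = obs_scale_km, obs_df = obs_df,
                 sigma_prior_sd = sigma_prior_sd,
                 mode_cutoff = mode_cutoff, seed = seed),
            class = "ssm_config")
}

#' Build the regular 8-h estimation grid for a track
#'
#' Nodes run from the first fix time in exact `step_hours` increments until
#' the last fix is covered; each fix is assigned to its enclosing interval
#' with a fractional offset in [0, 1] used for interpolation in the
#' observation model.
#'
#' @param track a track data.frame (column `time`).
#' @param step_hours grid spacing in hours.
#' @return list with `times` (POSIXct nodes), `interval` (0-based index per
#'   fix), `frac` (offset within interval), `step_hours`.
#' @export
build_time_grid <- function(track, step_hours = 8) {
  tsec <- as.numeric(track$time)
  span_h <- (max(tsec) - min(tsec)) / 3600
  if (span_h < 2 * step_hours)
    stop("track too short: need at least two grid steps of data")
  n_int <- ceiling(span_h / step_hours - 1e-9)
  t0 <- min(tsec)
  times <- as.POSIXct(t0 + (0:n_int) * step_hours * 3600,
                      origin = "1970-01-01", tz = "UTC")
  rel <- (tsec - t0) / (step_hours * 3600)
  interval <- pmin(floor(rel), n_int - 1)
  frac <- rel - interval
  list(times = times, interval = as.integer(interval), frac = frac,
       step_hours = step_hours)
}

#' Fit the two-state switching DCRW state-space model to one track
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler over latent regular-grid
#' positions, behavioural states, per-state move persistence and mean turn,
#' process covariance, and behaviour-switch probabilities. Location-class
#' observation scales are fixed at the configured values (the heavy-tailed t
#' observation model absorbs outliers). The migration state is identified as
#' the higher-persistence state through the ordering constraint
#' gamma_1 > gamma_2. Class-Z fixes must be removed beforehand (they are
#' dropped with a warning if present).
#'
#' @param track a filtered track data.frame (`time`, `lon`, `lat`, `lc`).
#' @param config an [ssm_config()].
#' @param proj an [albers_projection()] for the working plane.
#' @return An object of class `ssm_fit`: list with `path` (the StatePath
#'   data.frame: node time, lon/lat posterior mean and approximate 95%
#'   interval, behaviour mean `b_mean`, `mode` label), `params` (posterior
#'   summary per parameter), `chains` (retained samples per chain),
#'   `diagnostics` (PSRF/ESS from [check_convergence()]), and `grid`.
#' @export
fit_switching_dcrw <- function(track, config = ssm_config(), proj = albers_projection()) {
  if (any(track$lc == "Z")) {
    warning("class-Z fixes present; removing before fit")
    track <- track[track$lc != "Z", , drop = FALSE]
  }
  if (nrow(track) < 10) stop("too few fixes to fit the state-space model")
  grid <- build_time_grid(track, config$step_hours)
  N <- length(grid$times)
  pxy <- project_points(proj, track$lon, track$lat)
  psi <- pmax(as.numeric(config$obs_scale_km[track$lc]), 1e-3)
  nu <- as.numeric(config$obs_df[track$lc])
  if (anyNA(psi) || anyNA(nu))
    stop("observation scale/df missing for some location classes")

  # initial latent path: linear interpolation of fixes at node times
  tn <- as.numeric(grid$times)
  tf <- as.numeric(track$time)
  X0 <- stats::approx(tf, pxy$x, tn, rule = 2)$y
  Y0 <- stats::approx(tf, pxy$y, tn, rule = 2)$y
  d0 <- sqrt(diff(X0)^2 + diff(Y0)^2)
  b_init <- integer(N)
  b_init[2:N] <- ifelse(d0 > stats::median(d0), 1L, 2L)
  sd0 <- max(stats::sd(c(diff(X0), diff(Y0))) / 2, 0.5)

  run_chain <- function(chain) {
    # overdispersed inits: persistence levels and the foraging turn mode
    # (forward vs reversal) differ between chains
    g0 <- if (chain %% 2 == 1) c(0.7, 0.3) else c(0.9, 0.1)
    t20 <- if (chain %% 2 == 1) 0 else pi
    par0 <- c(g0, 0, t20, sd0, sd0, 0, 0.9, 0.1)
    jx <- X0 + stats::rnorm(N, 0, ifelse(chain == 1, 0, 0.5))
    jy <- Y0 + stats::rnorm(N, 0, ifelse(chain == 1, 0, 0.5))
    dcrw_chain(pxy$x, pxy$y, grid$interval, grid$frac, psi, nu,
               jx, jy, b_init, par0,
               config$n_iterations, config$burn_in, config$thin,
               config$sigma_prior_sd, 25)
  }
  chains <- with_seed(config$seed,
                      lapply(seq_len(config$n_chains), run_chain))

  samples <- lapply(chains, `[[`, "params")
  pooled <- do.call(rbind, samples)
  psum <- data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = apply(pooled, 2, stats::quantile, 0.025),
    q97.5 = apply(pooled, 2, stats::quantile, 0.975),
    row.names = NULL)

  w <- 1 / length(chains)
  xmean <- Reduce(`+`, lapply(chains, `[[`, "xmean")) * w
  ymean <- Reduce(`+`, lapply(chains, `[[`, "ymean")) * w
  xsd <- Reduce(`+`, lapply(chains, `[[`, "xsd")) * w
  ysd <- Reduce(`+`, lapply(chains, `[[`, "ysd")) * w
  bmean <- Reduce(`+`, lapply(chains, `[[`, "bmean")) * w

  ll <- unproject_points(proj, xmean, ymean)
  lo <- unproject_points(proj, xmean - 1.96 * xsd, ymean - 1.96 * ysd)
  hi <- unproject_points(proj, xmean + 1.96 * xsd, ymean + 1.96 * ysd)
  path <- data.frame(time = grid$times,
                     x = xmean, y = ymean,
                     lon = ll$lon, lat = ll$lat,
                     lon_lo = lo$lon, lon_hi = hi$lon,
                     lat_lo = lo$lat, lat_hi = hi$lat,
                     b_mean = bmean)
  path$mode <- classify_modes(path, cutoff = config$mode_cutoff)

  diagnostics <- if (length(samples) >= 2) check_convergence(samples) else NULL
  if (!is.null(diagnostics) && any(diagnostics$psrf > 1.1, na.rm = TRUE))
    warning("possible non-convergence: PSRF > 1.1 for ",
            paste(diagnostics$parameter[diagnostics$psrf > 1.1], collapse = ", "))

  structure(list(path = path, params = psum, chains = samples,
                 diagnostics = diagnostics, grid = grid, config = config,
                 proj = proj),
            class = "ssm_fit")
}

#' Classify behavioural modes from the posterior behaviour index
#'
#' A node is labelled `"foraging"` when its posterior mean behaviour index
#' (1 = migration, 2 = foraging) is at or above `cutoff`, else
#' `"migration"`. 1.5 is the symmetric binary choice.
#'
#' @param path a StatePath data.frame (or `ssm_fit`) with column `b_mean`.
#' @param cutoff classification threshold on [1, 2].
#' @return character vector of mode labels per node.
#' @export
classify_modes <- function(path, cutoff = 1.5) {
  if (inherits(path, "ssm_fit")) path <- path$path
  ifelse(path$b_mean >= cutoff, "foraging", "migration")
}

#' MCMC convergence diagnostics across chains
#'
#' Per-parameter potential scale reduction factor (split over chains) and a
#' pooled effective sample size from the initial-positive-sequence
#' autocorrelation estimator. PSRF above 1.1 flags non-convergence.
#'
#' @param chains list (length >= 2) of equal-size sample matrices, one per
#'   chain, columns = parameters.
#' @return data.frame with `parameter`, `psrf`, `ess`, `flag`.
#' @export
check_convergence <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("convergence diagnostics require at least two chains")
  m <- length(chains)
  n <- nrow(chains[[1]])
  p <- ncol(chains[[1]])
  nm <- colnames(chains[[1]]) %||% paste0("par", seq_len(p))
  psrf <- ess <- numeric(p)
  for (j in seq_len(p)) {
    draws <- sapply(chains, function(ch) ch[, j])        # n x m
    W <- mean(apply(draws, 2, stats::var))
    B_over_n <- stats::var(colMeans(draws))
    if (W < 1e-12) {                                      # degenerate chain
      psrf[j] <- 1
      ess[j] <- m * n
      next
    }
    vhat <- (n - 1) / n * W + B_over_n + B_over_n / m
    psrf[j] <- sqrt(vhat / W)
    rho_sum <- 0
    for (ci in seq_len(m)) {
      x <- draws[, ci]
      a <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
      pos <- which(a < 0.05)
      cut <- if (length(pos)) pos[1] - 1 else length(a)
      rho_sum <- rho_sum + (if (cut > 0) sum(a[seq_len(cut)]) else 0)
    }
    rho_bar <- rho_sum / m
    ess[j] <- m * n / (1 + 2 * max(rho_bar, 0))
  }
  data.frame(parameter = nm, psrf = psrf, ess = ess, flag = psrf > 1.1)
}
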