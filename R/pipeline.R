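#' Run the full foraging-area analysis pipeline on a simulated cohort
#'
#' End-to-end orchestration of the stages: environment + cohort simulation,
#' fix filtering, switching state-space model fit per animal, behavioural
#' segmentation and F/F1/F2/F3 site labelling, kernel core areas with LSCV
#' bandwidths, per-site fidelity tests, and the gridded habitat regression.
#' A single `seed` fans out to per-stage child seeds by fixed offsets, so
#' reruns with the same seed reproduce every table exactly.
#'
#' @param n_turtles cohort size.
#' @param duration_range per-animal tracking duration range (days).
#' @param seed master seed.
#' @param sim override [sim_config()] (then `n_turtles`/`duration_range`
#'   are ignored).
#' @param ssm an [ssm_config()]; defaults to the reduced desk preset so a
#'   cohort fits in minutes — pass `ssm_config()` for full production
#'   settings.
#' @param env optional pre-built `env_fields`.
#' @param min_kde_days minimum foraging-period length for site labelling/KDE.
#' @param min_kde_locs minimum mean daily locations for a KDE.
#' @param fidelity_n random-walk replicates per fidelity test.
#' @param subsample_fraction grid-cell subsampling fraction for the GLM.
#' @param out_dir optional directory; per-stage tables are written there as
#'   CSV (sites, fidelity, glm, summary).
#' @return list with `sites` (per-site table: label, arrival, days, daily
#'   locations, core area km^2, centroid, bathymetry and distances),
#'   `fidelity` (per-site proportion_higher and verdict), `grid`, `glm`
#'   (coefficient table or NULL), `summary` (named numeric vector),
#'   `turtles` (per-animal table), `env`, and `seed`.
#' @export
run_pipeline <- function(n_turtles = 5, duration_range = c(98, 342),
                         seed = 1, sim = NULL,
                         ssm = ssm_config(preset = "desk", seed = seed + 3),
                         env = NULL,
                         min_kde_days = 20, min_kde_locs = 10,
                         fidelity_n = 100, subsample_fraction = 0.2,
                         out_dir = NULL) {
  if (is.null(env)) env <- generate_environment(seed = seed + 1)
  proj <- env$proj
  cfg <- sim %||% sim_config(n_turtles = n_turtles,
                             duration_range = duration_range,
                             seed = seed + 2)
  cohort <- simulate_cohort(cfg, env)

  sites_rows <- list(); fid_rows <- list(); turtle_rows <- list()
  daily_all <- list()
  for (i in seq_along(cohort$fixes)) {
    fx <- cohort$fixes[[i]]
    if (nrow(fx) < 10) next
    filt <- filter_fixes(fx, env, mode_context = "any")
    fit <- tryCatch(fit_switching_dcrw(filt, ssm, proj = proj),
                    error = function(e) NULL)
    if (is.null(fit)) next
    segs <- segment_behavior(fit)
    sites <- label_foraging_sites(segs, turtle_id = fx$turtle_id[1],
                                  min_kde_days = min_kde_days)
    td <- travel_distances(filt)
    turtle_rows[[i]] <- data.frame(
      turtle_id = fx$turtle_id[1], site = cohort$meta$site[i],
      n_fixes = nrow(filt),
      tracking_days = sum(segs$duration_days),
      foraging_days = sum(segs$duration_days[segs$mode == "foraging"]),
      straight_km = td[["straight_line_km"]],
      total_km = td[["total_path_km"]])

    # mean daily foraging locations of every foraging segment feed the grid
    fsegs <- segs[segs$mode == "foraging", , drop = FALSE]
    for (s in seq_len(nrow(fsegs))) {
      sel <- filt$time >= fsegs$start[s] & filt$time <= fsegs$end[s]
      sf <- filter_fixes(filt[sel, , drop = FALSE], env,
                         mode_context = "foraging")
      md <- mean_daily_locations(sf)
      if (nrow(md) > 0) {
        md$turtle_id <- fx$turtle_id[1]
        md$period_days <- fsegs$duration_days[s]
        daily_all[[length(daily_all) + 1]] <- md
      }
    }

    for (s in seq_len(nrow(sites))) {
      sel <- filt$time >= sites$start[s] & filt$time <= sites$end[s]
      sf <- filter_fixes(filt[sel, , drop = FALSE], env,
                         mode_context = "foraging")
      md <- mean_daily_locations(sf)
      row <- data.frame(turtle_id = sites$turtle_id[s], label = sites$label[s],
                        arrival_date = sites$arrival_date[s],
                        duration_days = sites$duration_days[s],
                        n_daily_locations = nrow(md),
                        area_km2 = NA_real_, centroid_lon = NA_real_,
                        centroid_lat = NA_real_, bathy_m = NA_real_,
                        dist_land_km = NA_real_, dist_mainland_km = NA_real_)
      if (nrow(md) >= min_kde_locs) {
        pp <- project_points(proj, md$lon, md$lat)
        kde <- tryCatch({
          bw <- suppressWarnings(lscv_bandwidth(pp))
          water_fn <- function(x, y) {
            ll <- unproject_points(proj, x, y)
            b <- env_extract(env, "bathy", ll$lon, ll$lat)
            !is.na(b) & b < 0
          }
          kde_core_area(pp, bw$h, water_fn = water_fn)
        }, error = function(e) NULL)
        if (!is.null(kde)) {
          cen <- largest_center_centroid(kde, proj)
          row$area_km2 <- kde$area_km2
          row$centroid_lon <- cen[["lon"]]; row$centroid_lat <- cen[["lat"]]
          row$bathy_m <- env_extract(env, "bathy", cen[["lon"]], cen[["lat"]])
          row$dist_land_km <- distance_to_polygons_km(
            cen[["lon"]], cen[["lat"]], c(list(env$mainland), env$islands), proj)
          row$dist_mainland_km <- distance_to_polygon_km(
            cen[["lon"]], cen[["lat"]], env$mainland, proj)
        }
        fid <- tryCatch(
          site_fidelity_test(pp, env, proj, n = fidelity_n,
                             seed = seed + 50 + 17 * i + s),
          error = function(e) NULL)
        fid_rows[[length(fid_rows) + 1]] <- data.frame(
          turtle_id = sites$turtle_id[s], label = sites$label[s],
          proportion_higher = if (is.null(fid)) NA_real_ else fid$proportion_higher,
          fidelity = if (is.null(fid)) NA else fid$fidelity)
      }
      sites_rows[[length(sites_rows) + 1]] <- row
    }
  }
  sites_tab <- do.call(rbind, sites_rows)
  fid_tab <- do.call(rbind, fid_rows)
  turtles_tab <- do.call(rbind, turtle_rows)
  daily_tab <- do.call(rbind, daily_all)

  grid <- build_grid(env, proj,
                     release_points = cohort$meta[, c("release_lon", "release_lat")])
  glm_res <- NULL
  if (!is.null(daily_tab) && nrow(daily_tab) > 0) {
    grid <- count_foraging_days(daily_tab, grid, proj)
    sub <- subsample_cells(grid, subsample_fraction, seed = seed + 4)
    glm_res <- tryCatch(fit_log_glm(sub), error = function(e) NULL)
  }

  summary_vec <- pipeline_summary(turtles_tab, sites_tab, fid_tab, grid)
  out <- list(sites = sites_tab, fidelity = fid_tab, turtles = turtles_tab,
              daily = daily_tab, grid = grid,
              glm = if (!is.null(glm_res)) glm_res$table else NULL,
              summary = summary_vec, env = env, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
    wr(sites_tab, "sites.csv"); wr(fid_tab, "fidelity.csv")
    wr(turtles_tab, "turtles.csv"); wr(out$glm, "glm.csv")
    wr(grid, "grid.csv")
    wr(data.frame(statistic = names(summary_vec), value = summary_vec),
       "summary.csv")
  }
  out
}

# Summary layer: every number here is recomputed from the emitted tables.
pipeline_summary <- function(turtles, sites, fidelity, grid) {
  out <- c(n_turtles = if (is.null(turtles)) 0 else nrow(turtles))
  if (!is.null(turtles) && nrow(turtles) > 0) {
    out <- c(out,
      mean_travel_km = mean(turtles$straight_km),
      sd_travel_km = stats::sd(turtles$straight_km),
      total_tracking_days = sum(turtles$tracking_days),
      total_foraging_days = sum(turtles$foraging_days),
      pct_days_foraging = 100 * sum(turtles$foraging_days) /
        sum(turtles$tracking_days))
  }
  if (!is.null(sites) && nrow(sites) > 0) {
    for (lab in c("F", "F1", "F2", "F3")) {
      a <- sites$area_km2[sites$label == lab]
      out[paste0("mean_area_", lab, "_km2")] <-
        if (any(!is.na(a))) mean(a, na.rm = TRUE) else NA_real_
    }
    if (is.finite(out["mean_area_F_km2"] %||% NA)) {
      for (lab in c("F1", "F2", "F3")) {
        r <- out[paste0("mean_area_", lab, "_km2")] / out["mean_area_F_km2"]
        out[paste0(tolower(lab), "_f_area_ratio")] <- unname(r)
      }
    }
    out["mean_dist_land_km"] <- mean(sites$dist_land_km, na.rm = TRUE)
    out["mean_dist_mainland_km"] <- mean(sites$dist_mainland_km, na.rm = TRUE)
  }
  if (!is.null(fidelity) && nrow(fidelity) > 0)
    out["pct_sites_faf"] <- 100 * mean(fidelity$fidelity, na.rm = TRUE)
  if (!is.null(grid) && "days" %in% names(grid))
    out["grid_days_total"] <- sum(grid$days)
  out
}
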