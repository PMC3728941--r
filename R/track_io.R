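# Argos location classes ordered from best to worst quality; Z is invalid.
LC_LEVELS <- c("3", "2", "1", "0", "A", "B", "Z")

# Lenient ISO-8601 parsing: rows that match none of the accepted formats
# become NA (and are reported upstream) instead of aborting the read.
parse_utc_times <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Read a delimited table of Argos fixes into per-animal tracks
#'
#' Expects columns `turtle_id`, `utc_timestamp` (ISO-8601), `lon`, `lat`,
#' `lc`, optionally `true_state` (fixture ground truth). Rows are sorted by
#' time within animal; duplicate timestamps are resolved by keeping the fix
#' with the better location class (quality ordering 3 > 2 > 1 > 0 > A > B > Z).
#'
#' @param path file path.
#' @param sep field separator.
#' @param col_map optional named character vector remapping the expected
#'   column names to those present in the file, e.g.
#'   `c(turtle_id = "id", utc_timestamp = "date")`.
#' @return A named list of track data.frames (columns `turtle_id`, `time`,
#'   `lon`, `lat`, `lc`, and `true_state` when present), one per animal.
#' @export
read_argos_table <- function(path, sep = ",", col_map = NULL) {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("turtle_id", "utc_timestamp", "lon", "lat", "lc")
  for (nm in names(col_map)) names(raw)[names(raw) == col_map[[nm]]] <- nm
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty fix table: ", path)
    return(list())
  }
  time <- parse_utc_times(raw$utc_timestamp)
  lon <- as.numeric(raw$lon); lat <- as.numeric(raw$lat)
  bad <- is.na(time) | is.na(lon) | is.na(lat) | !(raw$lc %in% LC_LEVELS) |
    abs(lat) > 90 | abs(lon) > 180
  if (any(bad))
    warning(sum(bad), " unparseable or invalid rows dropped (lines ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
  df <- data.frame(turtle_id = raw$turtle_id, time = time, lon = lon, lat = lat,
                   lc = raw$lc, stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  if ("true_state" %in% names(raw))
    df$true_state <- as.integer(raw$true_state)[!bad]
  split_tracks <- split(df, df$turtle_id)
  lapply(split_tracks, function(tr) {
    tr <- tr[order(tr$time, match(tr$lc, LC_LEVELS)), , drop = FALSE]
    tr <- tr[!duplicated(tr$time), , drop = FALSE]      # best LC kept
    rownames(tr) <- NULL
    tr
  })
}

#' Write one or more tracks as a delimited table
#'
#' @param tracks a track data.frame or a list of them.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_tracks <- function(tracks, path, sep = ",") {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  all <- do.call(rbind, lapply(tracks, function(tr) {
    out <- data.frame(turtle_id = tr$turtle_id,
                      utc_timestamp = format(tr$time, "%Y-%m-%dT%H:%M:%S",
                                             tz = "UTC"),
                      lon = tr$lon, lat = tr$lat,
                      lc = if ("lc" %in% names(tr)) tr$lc else "3")
    if ("true_state" %in% names(tr)) out$true_state <- tr$true_state
    if ("state" %in% names(tr)) out$true_state <- tr$state
    out
  }))
  utils::write.table(all, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Filter implausible Argos fixes
#'
#' Removes invalid class-Z fixes always; with environmental fields supplied,
#' removes fixes on land (bathymetry > 0) and — in a foraging context only —
#' fixes in water deeper than `depth_limit_m` (biologically implausible for a
#' benthic forager). Spatially distant outliers are removed by a forward
#' speed filter: a fix is dropped when the speed from the last retained fix
#' exceeds `max_speed_kmh`. The filter is idempotent.
#'
#' @param track a track data.frame.
#' @param env optional `env_fields` for land/depth tests.
#' @param mode_context "any" (migration allowed over deep water) or
#'   "foraging" (apply the depth rule).
#' @param max_speed_kmh speed threshold for the distant-fix filter.
#' @param depth_limit_m depth cutoff (positive metres) in foraging context.
#' @return the filtered track, with attribute `n_removed` (named counts).
#' @export
filter_fixes <- function(track, env = NULL,
                         mode_context = c("any", "foraging"),
                         max_speed_kmh = 10, depth_limit_m = 100) {
  mode_context <- match.arg(mode_context)
  removed <- c(z = 0L, land = 0L, deep = 0L, speed = 0L, no_coverage = 0L)
  keep <- track$lc != "Z"
  removed["z"] <- sum(!keep)
  tr <- track[keep, , drop = FALSE]
  if (!is.null(env) && nrow(tr) > 0) {
    b <- env_extract(env, "bathy", tr$lon, tr$lat)
    out_cov <- is.na(b)
    if (any(out_cov)) {
      removed["no_coverage"] <- sum(out_cov)
      warning(sum(out_cov), " fixes outside raster coverage excluded")
    }
    land <- !out_cov & b > 0
    removed["land"] <- sum(land)
    deep <- if (mode_context == "foraging") !out_cov & b < -depth_limit_m
            else rep(FALSE, nrow(tr))
    removed["deep"] <- sum(deep)
    tr <- tr[!(out_cov | land | deep), , drop = FALSE]
  }
  if (nrow(tr) > 1 && is.finite(max_speed_kmh)) {
    keep_idx <- 1L
    last <- 1L
    for (i in 2:nrow(tr)) {
      dt_h <- as.numeric(difftime(tr$time[i], tr$time[last], units = "hours"))
      d_km <- great_circle_km(tr$lon[last], tr$lat[last], tr$lon[i], tr$lat[i])
      if (dt_h <= 0 || d_km / dt_h <= max_speed_kmh) {
        keep_idx <- c(keep_idx, i)
        last <- i
      }
    }
    removed["speed"] <- nrow(tr) - length(keep_idx)
    tr <- tr[keep_idx, , drop = FALSE]
  }
  rownames(tr) <- NULL
  attr(tr, "n_removed") <- removed
  tr
}

#' Mean daily locations
#'
#' One arithmetic-mean coordinate per UTC calendar day with at least one fix;
#' used to reduce temporal autocorrelation ahead of kernel density estimation
#' and the fidelity test.
#'
#' @param fixes a (filtered) track data.frame.
#' @return data.frame with columns `date`, `lon`, `lat`, `n_fixes`.
#' @export
mean_daily_locations <- function(fixes) {
  if (is.null(fixes) || nrow(fixes) == 0)
    return(data.frame(date = as.Date(character(0)), lon = numeric(0),
                      lat = numeric(0), n_fixes = integer(0)))
  day <- as.Date(fixes$time, tz = "UTC")
  agg <- stats::aggregate(cbind(lon, lat) ~ day, data = cbind(fixes, day = day),
                          FUN = mean)
  n <- as.vector(table(day)[as.character(agg$day)])
  out <- data.frame(date = agg$day, lon = agg$lon, lat = agg$lat, n_fixes = n)
  out[order(out$date), , drop = FALSE]
}

#' Straight-line and total travel distances
#'
#' Straight-line distance is the great-circle distance from the first fix
#' (release) to the last; total distance sums successive great-circle legs.
#'
#' @param track a track data.frame with at least two fixes.
#' @return named numeric vector `c(straight_line_km, total_path_km)`.
#' @export
travel_distances <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("travel distances undefined for tracks with fewer than 2 fixes")
  straight <- great_circle_km(track$lon[1], track$lat[1],
                              track$lon[n], track$lat[n])
  legs <- great_circle_km(track$lon[-n], track$lat[-n],
                          track$lon[-1], track$lat[-1])
  c(straight_line_km = straight, total_path_km = sum(legs))
}
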