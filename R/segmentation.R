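#' Segment a StatePath into maximal runs of constant behavioural mode
#'
#' @param path a StatePath data.frame (or `ssm_fit`) with columns `time` and
#'   `mode`.
#' @return data.frame of ordered segments: `segment`, `mode`, `start`, `end`
#'   (node times), `n_nodes`, `duration_days` (node count x step / 24).
#' @export
segment_behavior <- function(path) {
  if (inherits(path, "ssm_fit")) path <- path$path
  if (is.null(path) || nrow(path) == 0)
    return(data.frame(segment = integer(0), mode = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      n_nodes = integer(0), duration_days = numeric(0)))
  step_h <- if (nrow(path) > 1)
    as.numeric(difftime(path$time[2], path$time[1], units = "hours")) else 8
  r <- rle(path$mode)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(segment = seq_along(r$values), mode = r$values,
             start = path$time[starts], end = path$time[ends],
             n_nodes = r$lengths,
             duration_days = r$lengths * step_h / 24)
}

#' Label foraging sites F, F1, F2, F3
#'
#' The final foraging site (F) is the last segment of the track when that
#' segment is in foraging mode — the assumed final destination. Earlier
#' foraging segments of at least `min_kde_days` days are labelled F1, F2, F3
#' walking backwards in time (F1 used just prior to F, and so on). Tracks
#' ending in migration have no F; labelling then starts at F1 with the most
#' recent qualifying foraging segment. At most four sites are labelled.
#'
#' @param segments output of [segment_behavior()].
#' @param turtle_id identifier copied into the result.
#' @param min_kde_days minimum duration (days) for a pre-final site to be
#'   labelled (and later to enter kernel density estimation).
#' @return data.frame of labelled sites: `turtle_id`, `label`, `segment`,
#'   `start`, `end`, `duration_days`, `arrival_date`.
#' @export
label_foraging_sites <- function(segments, turtle_id = NA, min_kde_days = 20) {
  empty <- data.frame(turtle_id = character(0), label = character(0),
                      segment = integer(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_days = numeric(0),
                      arrival_date = as.Date(character(0)))
  if (nrow(segments) == 0) return(empty)
  labels <- character(0)
  rows <- integer(0)
  last <- nrow(segments)
  next_lab <- 0                     # 0 => F, then F1, F2, F3
  if (segments$mode[last] == "foraging") {
    labels <- "F"; rows <- last
  }
  next_lab <- 1
  cand <- rev(setdiff(which(segments$mode == "foraging"), rows))
  for (i in cand) {
    if (next_lab > 3) break
    if (segments$duration_days[i] >= min_kde_days) {
      labels <- c(labels, paste0("F", next_lab))
      rows <- c(rows, i)
      next_lab <- next_lab + 1
    }
  }
  if (length(rows) == 0) return(empty)
  out <- segments[rows, c("segment", "start", "end", "duration_days")]
  data.frame(turtle_id = turtle_id, label = labels, out,
             arrival_date = as.Date(out$start, tz = "UTC"),
             row.names = NULL)
}

#' Arrival date at a labelled foraging site
#'
#' The UTC date of the first grid node of the site's foraging segment.
#'
#' @param site one row of the [label_foraging_sites()] table (or any object
#'   with a `start` time).
#' @return a `Date`.
#' @export
arrival_date <- function(site) {
  as.Date(site$start, tz = "UTC")
}
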