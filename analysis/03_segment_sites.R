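#!/usr/bin/env Rscript
# Stage 3: turn the per-node behavioural modes into foraging periods, label
# the final (F) and prior (F1-F3) sites, and build the mean daily foraging
# locations (depth-filtered) that feed the home-range, fidelity, and grid
# stages.

source("analysis/00_config.R")

env <- build_env()
tracks <- read_argos_table(file.path(DATA_DIR, "argos_fixes.csv"))
sp <- utils::read.csv(file.path(OUT_DIR, "state_paths.csv"))
sp$time <- as.POSIXct(sp$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

sites <- list(); daily <- list(); seg_rows <- list()
for (id in unique(sp$turtle_id)) {
  path <- sp[sp$turtle_id == id, ]
  segs <- segment_behavior(path)
  seg_rows[[id]] <- cbind(turtle_id = id, segs)
  lab <- label_foraging_sites(segs, turtle_id = id)
  filt <- suppressWarnings(filter_fixes(tracks[[as.character(id)]], env))
  # every foraging period contributes daily locations; the site label (or
  # none) and the period duration travel along for the later filters
  fsegs <- segs[segs$mode == "foraging", , drop = FALSE]
  for (i in seq_len(nrow(fsegs))) {
    sel <- filt$time >= fsegs$start[i] & filt$time <= fsegs$end[i]
    ff <- suppressWarnings(filter_fixes(filt[sel, , drop = FALSE], env,
                                        mode_context = "foraging"))
    md <- mean_daily_locations(ff)
    if (nrow(md) == 0) next
    md$turtle_id <- id
    md$segment <- fsegs$segment[i]
    md$period_days <- fsegs$duration_days[i]
    md$label <- if (fsegs$segment[i] %in% lab$segment)
      lab$label[match(fsegs$segment[i], lab$segment)] else NA
    daily[[length(daily) + 1]] <- md
  }
  if (nrow(lab)) sites[[id]] <- lab
}

sites_tab <- do.call(rbind, sites)
daily_tab <- do.call(rbind, daily)
utils::write.csv(sites_tab, file.path(OUT_DIR, "sites.csv"), row.names = FALSE)
utils::write.csv(daily_tab, file.path(OUT_DIR, "daily_locations.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, seg_rows), file.path(OUT_DIR, "segments.csv"),
                 row.names = FALSE)

cat(sprintf("%d labelled foraging sites across %d animals (%s);\n",
            nrow(sites_tab), length(unique(sites_tab$turtle_id)),
            paste(names(table(sites_tab$label)), table(sites_tab$label),
                  sep = "=", collapse = ", ")))
cat(sprintf("%d mean daily foraging locations retained after depth/land filters.\n",
            nrow(daily_tab)))
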