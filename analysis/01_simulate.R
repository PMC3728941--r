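#!/usr/bin/env Rscript
# Stage 1: simulate the study system — a Gulf-like shelf environment and a
# 31-animal postnesting cohort with Argos-like observations — and write the
# raw inputs every later stage reads.

source("analysis/00_config.R")

env <- build_env()
cfg <- cohort_config()
cohort <- simulate_cohort(cfg, env)

write_tracks(cohort$fixes, file.path(DATA_DIR, "argos_fixes.csv"))
write_tracks(cohort$tracks, file.path(DATA_DIR, "true_tracks.csv"))
utils::write.csv(cohort$meta, file.path(DATA_DIR, "cohort_meta.csv"),
                 row.names = FALSE)
for (layer in c("bathy", "sst", "npp"))
  write_ascii_grid(env, layer, file.path(DATA_DIR, paste0(layer, ".asc")))
write_geojson_polygons(env$mainland, file.path(DATA_DIR, "mainland.geojson"))
if (length(env$islands))
  write_geojson_polygons(env$islands, file.path(DATA_DIR, "islands.geojson"))

n_fix <- sum(vapply(cohort$fixes, nrow, integer(1)))
cat(sprintf("Simulated %d animals (%.0f-%.0f tracking days), %d Argos fixes;\n",
            cfg$n_turtles, min(cohort$meta$duration_days),
            max(cohort$meta$duration_days), n_fix))
cat(sprintf("class-Z share %.1f%%; environment %d x %d cells written to %s\n",
            100 * mean(unlist(lapply(cohort$fixes, function(f) f$lc == "Z"))),
            length(env$lon), length(env$lat), DATA_DIR))
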