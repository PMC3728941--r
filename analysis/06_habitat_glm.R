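#!/usr/bin/env Rscript
# Stage 6: habitat regression. Pool every animal's daily foraging locations
# (periods >= 2 days) onto the 25 x 25 km grid bounded by the 100-m isobath,
# subsample 20% of cells against spatial correlation, and regress foraging
# days on the five environmental covariates with a log link.

source("analysis/00_config.R")

env <- build_env()
proj <- env$proj
daily <- utils::read.csv(file.path(OUT_DIR, "daily_locations.csv"))
meta <- utils::read.csv(file.path(DATA_DIR, "cohort_meta.csv"))

grid <- build_grid(env, proj,
                   release_points = meta[, c("release_lon", "release_lat")])
grid <- suppressWarnings(count_foraging_days(daily, grid, proj))
utils::write.csv(grid, file.path(OUT_DIR, "grid.csv"), row.names = FALSE)

sub <- subsample_cells(grid, 0.2, seed = MASTER_SEED + 4)
fit <- fit_log_glm(sub)
utils::write.csv(fit$table, file.path(OUT_DIR, "glm_table.csv"),
                 row.names = FALSE)

cat(sprintf("Grid: %d cells inside the 100-m isobath; %d turtle foraging days;\n",
            nrow(grid), sum(grid$days)))
cat(sprintf("regression on %d subsampled cells (%d with nonzero counts):\n",
            nrow(sub), sum(sub$days > 0)))
print(fit$table, digits = 3)
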