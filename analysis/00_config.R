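# Shared configuration for the analysis scripts. Everything downstream is a
# deterministic function of MASTER_SEED.

library(ridleyfaf)

MASTER_SEED <- 20100615
OUT_DIR <- "results"
DATA_DIR <- file.path(OUT_DIR, "data")

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

# Cohort of 31 postnesting animals tracked 98-342 days (the study's design),
# observed through the 6 h on / 6 h off Argos duty cycle.
cohort_config <- function() sim_config(n_turtles = 31, seed = MASTER_SEED + 2)

build_env <- function() generate_environment(seed = MASTER_SEED + 1)

# Reduced sampler settings keep the 31-animal fit to a few minutes; swap in
# ssm_config(seed = ...) for the full production settings (10,000 retained,
# 7000 burn-in, thinned by 5).
ssm_settings <- function() ssm_config(preset = "desk", seed = MASTER_SEED + 3)
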