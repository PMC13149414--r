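#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic mortality panel.
#
# Emulates the study design the model targets: 7 EAC countries on their
# land-border contiguity graph, 4 NCD groups, 20 years (2000-2019), eight
# spatio-temporally autocorrelated covariates, latent effects drawn from the
# model's own priors, and Poisson death counts around expected deaths.
# Writes results/panel.csv and results/truth_synthetic.csv.

library(sharedmap)

seed <- 20260921 %% 10000
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_panel(cfg)

write_panel_csv(sim$panel, "results/panel.csv")
write_truth_csv(sim$truth, "results/truth_synthetic.csv")
saveRDS(sim, "scratch/sim.rds")

message(sprintf(
  "Simulated a balanced panel of %d observations (%d countries x %d diseases x %d years).",
  nrow(sim$panel), length(attr(sim$panel, "countries")),
  length(attr(sim$panel, "diseases")), length(attr(sim$panel, "years"))))
message(sprintf("Death counts span %d-%d; expected deaths %.0f-%.0f.",
                min(sim$panel$deaths), max(sim$panel$deaths),
                min(sim$panel$expected_deaths), max(sim$panel$expected_deaths)))
message("True fixed effects (standardized scale): ",
        paste(sprintf("%s=%.2f", names(cfg$beta), cfg$beta), collapse = ", "))
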