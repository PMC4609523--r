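#!/usr/bin/env Rscript

# Stage 4: preprocessing. Regenerates the panel's cutout images (the
# raster set is a deterministic function of the stage-1 seed) and runs
# the full pipeline — 2500 um^2 crop, Gaussian sigma = 1, bilinear
# downsampling to 50 x 50, HSV conversion with V dropped — producing one
# 5000-entry hue/saturation vector per cutout.

suppressPackageStartupMessages(library(ctcnoise))

SEED <- 20260930L

cal <- read.csv("results/synth/calibration.csv")
mix <- difficulty_mixture(cal$ambiguous_mass)
profiles <- default_observer_panel(uncertainty_slope = cal$uncertainty_slope)
pan <- generate_panel(617, profiles, mix, seed = SEED + 1)

t0 <- Sys.time()
feats <- preprocess_batch(pan$cutouts, preprocess_config())
message(sprintf("preprocessed %d cutouts to %d features in %.1f s",
                nrow(feats), ncol(feats),
                as.numeric(Sys.time() - t0, units = "secs")))

dir.create("scratch", showWarnings = FALSE)
saveRDS(feats, "scratch/features.rds")
# small text excerpt for inspection
write.csv(round(feats[1:5, c(1:6, 2501:2506)], 4),
          "results/features_excerpt.csv")
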