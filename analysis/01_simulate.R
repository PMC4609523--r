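#!/usr/bin/env Rscript

# Stage 1: calibrate the synthetic-data generator to the agreement regime
# of the eleven-observer CTC annotation study (mean pairwise agreement
# 0.85, consensus fraction 0.81) and generate the working panel:
# 617 cutouts, 9 neutral + 2 conservative observers. Writes the
# annotation matrix, scene metadata and a few example images.

suppressPackageStartupMessages(library(ctcnoise))

SEED <- 20260930L
N_POINTS <- 617L

dir.create("results/synth/cutouts", recursive = TRUE, showWarnings = FALSE)

message("calibrating difficulty mixture ...")
cal <- calibrate_difficulty(target_agreement = 0.85,
                            target_consensus_fraction = 0.81,
                            seed = SEED)
message(sprintf("  ambiguous mass %.3f, slope %.2f -> agreement %.3f, consensus %.3f",
                cal$mixture$ambiguous_mass, cal$uncertainty_slope,
                cal$achieved_agreement, cal$achieved_consensus_fraction))
write.csv(data.frame(
  ambiguous_mass = cal$mixture$ambiguous_mass,
  uncertainty_slope = cal$uncertainty_slope,
  achieved_agreement = cal$achieved_agreement,
  achieved_consensus_fraction = cal$achieved_consensus_fraction),
  "results/synth/calibration.csv", row.names = FALSE)

message("generating panel ...")
pan <- generate_panel(N_POINTS, cal$profiles, cal$mixture, seed = SEED + 1)

write_annotation_matrix(pan$ann, "results/synth/annotations.csv")
write.csv(data.frame(
  cutout_id = pan$ann$cutout_ids,
  truth = pan$truth,
  difficulty = pan$difficulty,
  pixel_area_um2 = vapply(pan$scenes, `[[`, numeric(1), "pixel_area")),
  "results/synth/scenes.csv", row.names = FALSE)

# a handful of example images across the difficulty range
ord <- order(pan$difficulty)
show <- c(ord[1:3], ord[(N_POINTS - 2):N_POINTS])
for (i in show)
  write_cutout(pan$cutouts[[i]],
               sprintf("results/synth/cutouts/%s.png", pan$ann$cutout_ids[i]))

message(sprintf("panel written: %d cutouts, %d observers, %d CTC-true scenes",
                pan$ann$N, pan$ann$M, sum(pan$truth)))
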