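#!/usr/bin/env Rscript

# Stage 3: consensus construction. Tabulates the consensus limit as a
# function of panel size, partitions the simulated panel into consensus /
# total-consensus (GT) / probabilistic (probGT) strata, and quantifies
# the label instability of probGT annotations.

suppressPackageStartupMessages(library(ctcnoise))

ann <- read_annotation_matrix("results/synth/annotations.csv")

limits <- data.frame(n_observers = 2:25)
limits$consensus_limit <- vapply(limits$n_observers, consensus_limit,
                                 integer(1), alpha = 0.05)
write.csv(limits, "results/consensus_limits.csv", row.names = FALSE)

cfg <- consensus_config(ann$M, alpha = 0.05)
part <- build_partition(ann, cfg)
print(part)
write.csv(partition_table(part, ann), "results/partition.csv",
          row.names = FALSE)

elc <- expected_label_changes(ann, part$probgt_indices)
cat(sprintf(paste0(
  "consensus limit c = %d of %d observers\n",
  "consensus on %d of %d cutouts (%.1f%%); GT %d, probGT %d\n",
  "expected label changes between two probabilistic annotations: %.1f\n"),
  cfg$c, ann$M, sum(part$consensus_mask), ann$N,
  100 * mean(part$consensus_mask), length(part$gt_indices),
  length(part$probgt_indices), elc))
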