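#!/usr/bin/env Rscript

# Stage 5: label-noise experiments. Runs (i) the cross-observer
# whole-set evaluation — five folds per observer annotation, averaged
# across observers — and (ii) the GT/probGT training grid: train on two
# folds drawn from the clean (GT) and probabilistic (probGT) strata in
# all combinations, always testing on a held-out GT fold. probGT
# training labels are redrawn every repetition.

suppressPackageStartupMessages(library(ctcnoise))

SEED <- 20260930L
N_REP_GT <- 10L      # pure-GT condition: only forest construction varies
N_REP_PROB <- 50L    # conditions that resample probabilistic annotations

ann <- read_annotation_matrix("results/synth/annotations.csv")
feats <- readRDS("scratch/features.rds")
part <- build_partition(ann, consensus_config(ann$M))
specs <- list(RF = classifier_spec("random_forest"),
              SVM = classifier_spec("svm_rbf"))

message("noise grid ...")
t0 <- Sys.time()
grid <- run_noise_grid(feats, part, ann, specs,
                       n_repetitions = c(train_2GT = N_REP_GT,
                                         train_1GT_1probGT = N_REP_PROB,
                                         train_2probGT = N_REP_PROB),
                       seed = SEED + 2)
message(sprintf("  done in %.1f min", as.numeric(Sys.time() - t0, units = "mins")))
write.csv(grid$runs, "results/noise_grid_runs.csv", row.names = FALSE)
s <- grid$summary
s[, -(1:3)] <- round(s[, -(1:3)], 2)
write.csv(s, "results/noise_grid_summary.csv", row.names = FALSE)
print(s)

message("cross-observer whole-set evaluation ...")
t0 <- Sys.time()
xo <- run_cross_observer(feats, ann, specs, n_folds = 5, seed = SEED + 3)
message(sprintf("  done in %.1f min", as.numeric(Sys.time() - t0, units = "mins")))
write.csv(xo$per_observer, "results/cross_observer_per_observer.csv",
          row.names = FALSE)
xs <- xo$summary
xs[, -(1:2)] <- round(xs[, -(1:2)], 2)
write.csv(xs, "results/cross_observer_summary.csv", row.names = FALSE)
print(xs)
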