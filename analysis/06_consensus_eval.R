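#!/usr/bin/env Rscript

# Stage 6: evaluation against the consensus annotation. Classifiers are
# cross-validated on the consensus data set (four folds) against
# consensus labels; every observer's raw annotation is scored against
# the same reference. Also demonstrates the paper-level point that
# scoring the same predictions against probabilistic test labels
# understates performance.

suppressPackageStartupMessages({
  library(ctcnoise)
  library(ggplot2)
})

SEED <- 20260930L

ann <- read_annotation_matrix("results/synth/annotations.csv")
feats <- readRDS("scratch/features.rds")
part <- build_partition(ann, consensus_config(ann$M))
specs <- list(RF = classifier_spec("random_forest"),
              SVM = classifier_spec("svm_rbf"))

res <- run_consensus_eval(feats, part, ann, specs, n_folds = 4,
                          seed = SEED + 4)
write.csv(res$classifiers, "results/consensus_eval_classifiers.csv",
          row.names = FALSE)
write.csv(res$observers, "results/consensus_eval_observers.csv",
          row.names = FALSE)
print(res$classifiers)

long <- rbind(
  data.frame(who = res$observers$observer_id, kind = "observer",
             accuracy = res$observers$accuracy,
             precision = res$observers$precision,
             recall = res$observers$recall),
  data.frame(who = res$classifiers$classifier, kind = "classifier",
             accuracy = res$classifiers$accuracy,
             precision = res$classifiers$precision,
             recall = res$classifiers$recall))
long <- reshape(long, direction = "long",
                varying = c("accuracy", "precision", "recall"),
                v.names = "value", times = c("accuracy", "precision", "recall"),
                timevar = "measure")
p <- ggplot(long, aes(measure, value, colour = kind, group = who)) +
  geom_point(position = position_jitter(width = 0.08, height = 0), size = 2) +
  labs(y = "performance vs consensus labels", x = NULL) +
  theme_bw()
ggsave("results/consensus_eval.png", p, width = 6, height = 4, dpi = 150)

# consensus vs probabilistic test labels for one fitted model
cons_idx <- which(part$consensus_mask)
fa <- make_folds(cons_idx, 4, seed = SEED + 5)
test_idx <- fa$indices[fa$fold == 1]
train_idx <- fa$indices[fa$fold != 1]
for (cl in names(specs)) {
  m <- train_classifier(specs[[cl]], feats[train_idx, ],
                        part$consensus_labels[train_idx])
  pred <- predict_labels(m, feats[test_idx, ])
  acc_cons <- mean(pred == part$consensus_labels[test_idx])
  acc_prob <- mean(vapply(1:20, function(r) {
    mean(pred == sample_probabilistic_annotation(ann, test_idx,
                                                 seed = SEED + 100 + r))
  }, numeric(1)))
  cat(sprintf("%s: accuracy vs consensus labels %.3f, vs probabilistic labels %.3f\n",
              cl, acc_cons, acc_prob))
}
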