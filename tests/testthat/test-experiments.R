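# Feature matrix perfectly informative about a label vector.
features_for <- function(labels, seed, gap = 4) {
  withr::with_seed(seed, {
    x <- cbind(rnorm(length(labels), gap * labels),
               rnorm(length(labels), -gap * labels))
    colnames(x) <- c("f1", "f2")
    x
  })
}

# 2-D toys need a wider RBF than the 5000-dim default.
toy_specs <- function() {
  list(RF = classifier_spec("random_forest", seed = 1),
       SVM = classifier_spec("svm_rbf", C = 2, gamma = 0.05))
}

test_that("folds are balanced, exhaustive and reproducible", {
  fa <- make_folds(1:10, 5, seed = 3)
  expect_equal(as.integer(table(fa$fold)), rep(2L, 5))

  fa <- make_folds(1:617, 5, seed = 4)
  expect_setequal(as.integer(table(fa$fold)), c(123L, 124L))
  expect_setequal(fa$indices, 1:617)

  expect_identical(make_folds(1:20, 4, seed = 9), make_folds(1:20, 4, seed = 9))
  expect_error(make_folds(1:3, 5, seed = 1), "more folds")
})

test_that("cross-observer evaluation is perfect for identical observers on
           separable features", {
  labels <- rep(c(0L, 1L), 25)
  ann <- annotation_matrix(cbind(A = labels, B = labels, C = labels))
  feats <- features_for(labels, seed = 5)
  res <- run_cross_observer(feats, ann, toy_specs(), n_folds = 5, seed = 6)
  expect_equal(res$summary$accuracy_mean, c(1, 1))
  expect_equal(res$summary$accuracy_sd, c(0, 0))
  expect_equal(nrow(res$per_observer), 6)  # 3 observers x 2 classifiers
  expect_error(run_cross_observer(feats[1:10, ], ann, toy_specs()),
               "aligned")
})

test_that("noise grid runs all conditions, is deterministic, and training on
           clean consensus labels scores highly", {
  withr::with_seed(21, {
    truth <- rbinom(100, 1, 0.5)
    # 5 observers: mostly truth, some dissent on a third of the points
    hard <- rbinom(100, 1, 0.35) == 1
    labs <- sapply(1:5, function(j)
      ifelse(hard & rbinom(100, 1, 0.4) == 1, 1L - truth, truth))
  })
  ann <- annotation_matrix(labs)
  part <- build_partition(ann, consensus_config(5))
  expect_gt(length(part$probgt_indices), 2)
  feats <- features_for(truth, seed = 22)
  g1 <- run_noise_grid(feats, part, ann, toy_specs(), n_repetitions = 2,
                       seed = 23)
  g2 <- run_noise_grid(feats, part, ann, toy_specs(), n_repetitions = 2,
                       seed = 23)
  expect_identical(g1$runs, g2$runs)
  expect_setequal(unique(g1$runs$condition),
                  c("train_2GT", "train_1GT_1probGT", "train_2probGT"))
  # 3 conditions x 2 reps x 3 rotations x 2 classifiers
  expect_equal(nrow(g1$runs), 36)
  gt_acc <- g1$summary$accuracy_mean[g1$summary$condition == "train_2GT"]
  expect_true(all(gt_acc >= 0.9))
})

test_that("an all-unanimous panel collapses every condition to pure-GT
           training", {
  labels <- rep(c(0L, 1L), 30)
  ann <- annotation_matrix(sapply(1:5, function(j) labels))
  part <- build_partition(ann, consensus_config(5))
  expect_length(part$probgt_indices, 0)
  feats <- features_for(labels, seed = 31)
  g <- run_noise_grid(feats, part, ann, toy_specs(), n_repetitions = 2,
                      seed = 32)
  s <- g$summary
  for (cl in unique(s$classifier)) {
    accs <- s$accuracy_mean[s$classifier == cl]
    expect_lt(diff(range(accs)), 1e-9)
  }
})

test_that("consensus evaluation scores observers and classifiers against
           consensus labels", {
  # unanimous rows plus dissent rows; observer A always votes the majority
  withr::with_seed(41, {
    truth <- rep(c(0L, 1L), each = 60)[sample.int(120)]
    labs <- sapply(1:5, function(j) truth)
    flip <- sample.int(120, 25)
    labs[flip, 3] <- 1L - labs[flip, 3]   # observer C dissents sometimes
  })
  ann <- annotation_matrix(labs)
  part <- build_partition(ann, consensus_config(5))
  feats <- features_for(truth, seed = 42)
  res <- run_consensus_eval(feats, part, ann, toy_specs(), seed = 43)
  obs <- res$observers
  expect_equal(obs$accuracy[obs$observer_id == "V1"], 1)
  expect_equal(obs$precision[obs$observer_id == "V1"], 1)
  expect_equal(obs$recall[obs$observer_id == "V1"], 1)
  # separable features: cross-validated classifiers near-perfect
  expect_true(all(res$classifiers$accuracy >= 0.98))
})

test_that("a conservative observer shows recall below precision against
           consensus", {
  pan <- generate_panel(400, default_observer_panel(),
                        difficulty_mixture(0.45), seed = 51, images = FALSE)
  part <- build_partition(pan$ann, consensus_config(11))
  cons_idx <- which(part$consensus_mask)
  ref <- part$consensus_labels[cons_idx]
  sc <- score_predictions(pan$ann$labels[cons_idx, "C01"], ref)
  expect_lt(sc$recall, sc$precision)
})
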