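#' Randomized balanced folds
#'
#' Partitions an index set into `n_folds` folds whose sizes differ by at
#' most one, uniformly at random, reproducibly under the seed.
#'
#' @param indices Integer vector of data-point indices.
#' @param n_folds Number of folds (<= `length(indices)`).
#' @param seed Integer RNG seed.
#' @return A list of class `fold_assignment` with `indices`, `fold`
#'   (fold id per index), `n_folds`, `seed`.
#' @export
make_folds <- function(indices, n_folds, seed) {
  n <- length(indices)
  n_folds <- as.integer(n_folds)
  if (n_folds > n)
    stop("more folds than data points", call. = FALSE)
  fold <- withr::with_seed(seed, {
    ids <- rep(seq_len(n_folds), length.out = n)
    ids[sample.int(n)]
  })
  structure(list(indices = indices, fold = fold, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

# Indices belonging to the given fold(s).
fold_members <- function(fa, which_folds) {
  fa$indices[fa$fold %in% which_folds]
}

# Fit a spec (with a derived forest seed) and score its predictions on a
# held-out set, verifying train/test disjointness.
fit_and_score <- function(spec, features, train_idx, train_labels,
                          test_idx, test_labels, seed) {
  stopifnot(length(intersect(train_idx, test_idx)) == 0L)
  sp <- spec
  sp$seed <- seed
  model <- train_classifier(sp, features[train_idx, , drop = FALSE],
                            train_labels)
  pred <- predict_labels(model, features[test_idx, , drop = FALSE])
  score_predictions(pred, test_labels)
}

#' Cross-observer whole-set evaluation
#'
#' For each observer's annotation in turn, the full data set is split
#' into five randomized folds; in each of five rotations one fold is
#' tested, the cyclically next fold is left out entirely, and the
#' classifier is trained on the remaining three, so every point is
#' classified exactly once per sweep. Confusion counts are pooled per
#' observer and the performance measures are then averaged (with SD)
#' across observers per classifier.
#'
#' @param features Feature matrix, rows aligned with the annotation
#'   matrix.
#' @param ann An [annotation_matrix()].
#' @param specs Named list of [classifier_spec()] objects.
#' @param n_folds Number of folds (default 5).
#' @param seed Master seed (folds and forest seeds derive from it).
#' @return A list with `per_observer` (data frame: classifier,
#'   observer_id, accuracy, precision, recall) and `summary` (data frame
#'   of mean and SD across observers per classifier).
#' @export
run_cross_observer <- function(features, ann, specs, n_folds = 5, seed = 1) {
  stopifnot(inherits(ann, "annotation_matrix"))
  features <- as.matrix(features)
  if (nrow(features) != ann$N)
    stop("features not row-aligned with annotation matrix", call. = FALSE)
  fa <- make_folds(seq_len(ann$N), n_folds, derive_seed(seed, 0))
  rows <- list()
  for (si in seq_along(specs)) {
    sname <- names(specs)[si]
    for (obs in seq_len(ann$M)) {
      labels <- ann$labels[, obs]
      scores <- vector("list", n_folds)
      for (t in seq_len(n_folds)) {
        excluded <- (t %% n_folds) + 1L
        train_folds <- setdiff(seq_len(n_folds), c(t, excluded))
        train_idx <- fold_members(fa, train_folds)
        test_idx <- fold_members(fa, t)
        scores[[t]] <- fit_and_score(
          specs[[si]], features, train_idx, labels[train_idx],
          test_idx, labels[test_idx], derive_seed(seed, si, obs, t))
      }
      pooled <- pool_scores(scores)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = sname, observer_id = ann$observer_ids[obs],
        accuracy = pooled$accuracy, precision = pooled$precision,
        recall = pooled$recall, stringsAsFactors = FALSE)
    }
  }
  per_obs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_obs, per_obs$classifier), function(d)
    data.frame(classifier = d$classifier[1],
               n_observers = nrow(d),
               accuracy_mean = mean(d$accuracy),
               accuracy_sd = stats::sd(d$accuracy),
               precision_mean = mean(d$precision),
               precision_sd = stats::sd(d$precision),
               recall_mean = mean(d$recall),
               recall_sd = stats::sd(d$recall),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(per_observer = per_obs, summary = summ,
       folds = fa)
}

#' Label-noise training grid over GT and probGT folds
#'
#' The total-consensus points (GT, labels fixed) are split into three
#' folds and the non-unanimous points (probGT) into two. Training uses
#' two folds per the condition — both GT, one of each, or both probGT —
#' and testing always uses a GT fold not used for training, rotated over
#' all three GT folds. probGT training labels are freshly sampled
#' probabilistic annotations in every repetition; GT repetitions only
#' re-randomize the forest construction.
#'
#' Fold schedule: when GT fold t is tested, condition
#' `train_1GT_1probGT` trains on GT fold `(t mod 3) + 1` and probGT fold
#' `((t + r) mod 2) + 1` for repetition r, so both probGT folds are
#' exercised. If the annotation is entirely unanimous (probGT empty)
#' there is no uncertain stratum and every condition collapses to
#' pure-GT training.
#'
#' @param features Feature matrix aligned with `ann`.
#' @param partition A [build_partition()] result.
#' @param ann The matching [annotation_matrix()].
#' @param specs Named list of [classifier_spec()] objects.
#' @param n_repetitions Repetitions per condition; either a single number
#'   or a vector named by condition. Defaults to 10 for the fixed-label
#'   `train_2GT` condition and 50 for the conditions that resample
#'   probabilistic annotations.
#' @param conditions Subset of
#'   `c("train_2GT", "train_1GT_1probGT", "train_2probGT")`.
#' @param seed Master seed.
#' @return A list with `runs` (one row per condition x classifier x
#'   repetition x rotation) and `summary` (mean and SD of Acc/Pre/Rec
#'   over repetitions x rotations per condition and classifier).
#' @export
run_noise_grid <- function(features, partition, ann, specs,
                           n_repetitions = c(train_2GT = 10,
                                             train_1GT_1probGT = 50,
                                             train_2probGT = 50),
                           conditions = c("train_2GT", "train_1GT_1probGT",
                                          "train_2probGT"),
                           seed = 1) {
  stopifnot(inherits(partition, "consensus_partition"),
            inherits(ann, "annotation_matrix"))
  features <- as.matrix(features)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (length(n_repetitions) == 1L && is.null(names(n_repetitions)))
    n_repetitions <- stats::setNames(rep(n_repetitions, length(conditions)),
                                     conditions)
  if (length(partition$gt_indices) < 3L)
    stop("too few GT points for the fold design", call. = FALSE)
  # with no uncertain data every condition degenerates to pure-GT training
  collapse <- length(partition$probgt_indices) < 2L
  gt_folds <- make_folds(partition$gt_indices, 3L, derive_seed(seed, 101))
  pg_folds <- if (collapse) NULL
              else make_folds(partition$probgt_indices, 2L,
                              derive_seed(seed, 102))
  gt_labels <- partition$consensus_labels  # defined on GT by construction

  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    n_rep <- n_repetitions[[cond]]
    for (r in seq_len(n_rep)) {
      # one probabilistic annotation per repetition, shared across rotations
      pg_label_of <- if (collapse) NULL else {
        pg_ann <- sample_probabilistic_annotation(
          ann, partition$probgt_indices, derive_seed(seed, 200, r))
        stats::setNames(pg_ann, partition$probgt_indices)
      }
      for (t in 1:3) {
        test_idx <- fold_members(gt_folds, t)
        test_labels <- gt_labels[test_idx]
        if (cond == "train_2GT" || collapse) {
          train_idx <- fold_members(gt_folds, setdiff(1:3, t))
          train_labels <- gt_labels[train_idx]
        } else if (cond == "train_1GT_1probGT") {
          g <- (t %% 3L) + 1L
          pb <- ((t + r) %% 2L) + 1L
          gt_part <- fold_members(gt_folds, g)
          pg_part <- fold_members(pg_folds, pb)
          train_idx <- c(gt_part, pg_part)
          train_labels <- c(gt_labels[gt_part],
                            pg_label_of[as.character(pg_part)])
        } else {
          train_idx <- fold_members(pg_folds, 1:2)
          train_labels <- pg_label_of[as.character(train_idx)]
        }
        for (si in seq_along(specs)) {
          # in collapsed (GT-only) mode all conditions see identical data;
          # sharing the forest seed keeps their reports identical too
          ci_eff <- if (collapse) 1L else ci
          sc <- fit_and_score(specs[[si]], features,
                              train_idx, unname(train_labels),
                              test_idx, test_labels,
                              derive_seed(seed, ci_eff, r, t, si))
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, classifier = names(specs)[si],
            repetition = r, rotation = t,
            accuracy = sc$accuracy, precision = sc$precision,
            recall = sc$recall, stringsAsFactors = FALSE)
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(runs, list(runs$condition, runs$classifier), drop = TRUE),
    function(d) data.frame(
      condition = d$condition[1], classifier = d$classifier[1],
      n_runs = nrow(d),
      accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
      precision_mean = mean(d$precision, na.rm = TRUE),
      precision_sd = stats::sd(d$precision, na.rm = TRUE),
      recall_mean = mean(d$recall, na.rm = TRUE),
      recall_sd = stats::sd(d$recall, na.rm = TRUE),
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ, gt_folds = gt_folds,
       probgt_folds = pg_folds)
}

#' Consensus-set evaluation of classifiers and observers
#'
#' Cross-validates the classifiers on the consensus data set (points
#' where at least c observers agree) against the consensus labels — four
#' folds, train on three, test on the fourth, rotating — and scores each
#' observer's raw annotation against the same consensus labels. Note the
#' caveat that every observer voted in the consensus, while the
#' classifiers did not.
#'
#' @param features Feature matrix aligned with `ann`.
#' @param partition A [build_partition()] result.
#' @param ann The matching [annotation_matrix()].
#' @param specs Named list of [classifier_spec()] objects.
#' @param n_folds Number of folds (default 4).
#' @param seed Master seed.
#' @return A list with `classifiers` (pooled Acc/Pre/Rec per classifier)
#'   and `observers` (Acc/Pre/Rec per observer against consensus labels).
#' @export
run_consensus_eval <- function(features, partition, ann, specs,
                               n_folds = 4, seed = 1) {
  stopifnot(inherits(partition, "consensus_partition"),
            inherits(ann, "annotation_matrix"))
  features <- as.matrix(features)
  cons_idx <- which(partition$consensus_mask)
  if (length(cons_idx) < n_folds)
    stop("consensus set smaller than the number of folds", call. = FALSE)
  labels <- partition$consensus_labels[cons_idx]
  fa <- make_folds(cons_idx, n_folds, derive_seed(seed, 301))
  cls <- list()
  for (si in seq_along(specs)) {
    scores <- vector("list", n_folds)
    for (t in seq_len(n_folds)) {
      train_idx <- fold_members(fa, setdiff(seq_len(n_folds), t))
      test_idx <- fold_members(fa, t)
      scores[[t]] <- fit_and_score(
        specs[[si]], features,
        train_idx, partition$consensus_labels[train_idx],
        test_idx, partition$consensus_labels[test_idx],
        derive_seed(seed, 300, si, t))
    }
    pooled <- pool_scores(scores)
    cls[[si]] <- data.frame(
      classifier = names(specs)[si], accuracy = pooled$accuracy,
      precision = pooled$precision, recall = pooled$recall,
      stringsAsFactors = FALSE)
  }
  obs <- lapply(seq_len(ann$M), function(j) {
    sc <- score_predictions(ann$labels[cons_idx, j], labels)
    data.frame(observer_id = ann$observer_ids[j], accuracy = sc$accuracy,
               precision = sc$precision, recall = sc$recall,
               stringsAsFactors = FALSE)
  })
  list(classifiers = do.call(rbind, cls), observers = do.call(rbind, obs),
       folds = fa)
}
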