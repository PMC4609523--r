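#' Classifier specification
#'
#' The two classifiers studied: a Breiman random forest (500 trees,
#' `floor(sqrt(p))` candidate features per split, unlimited depth) and a
#' soft-margin SVM with radial basis function kernel
#' \eqn{k(x, y) = \exp(-\gamma \|x - y\|^2)}, C = 2, gamma = 0.005. The
#' parameter values are the study's settings and are not tuned here.
#'
#' @param kind `"random_forest"` or `"svm_rbf"`.
#' @param n_trees Number of trees (random forest only).
#' @param C Soft-margin penalty (SVM only).
#' @param gamma Inverse RBF radius (SVM only).
#' @param seed Integer seed for the stochastic forest construction.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("random_forest", "svm_rbf"),
                            n_trees = 500, C = 2, gamma = 0.005, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "random_forest") {
    stopifnot(n_trees >= 1)
    structure(list(kind = kind, n_trees = as.integer(n_trees),
                   seed = as.integer(seed)),
              class = "classifier_spec")
  } else {
    stopifnot(C > 0, gamma > 0)
    structure(list(kind = kind, C = C, gamma = gamma,
                   seed = as.integer(seed)),
              class = "classifier_spec")
  }
}

#' Train a binary classifier on feature vectors
#'
#' @param spec A [classifier_spec()].
#' @param features Numeric matrix, one row per data point.
#' @param labels Binary vector (0/1), one per row; both classes must be
#'   present.
#' @return A fitted-model handle of class `ctc_classifier`.
#' @export
train_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("features and labels differ in length", call. = FALSE)
  assert_binary(labels, "training labels")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%05d", seq_len(ncol(features)))
  y <- factor(labels, levels = c(0, 1))
  fit <- switch(spec$kind,
    random_forest = ranger::ranger(
      x = features, y = y, num.trees = spec$n_trees,
      num.threads = 1L, seed = spec$seed, classification = TRUE),
    svm_rbf = kernlab::ksvm(
      features, y, type = "C-svc", kernel = "rbfdot",
      kpar = list(sigma = spec$gamma), C = spec$C, scaled = FALSE)
  )
  structure(list(spec = spec, fit = fit, p = ncol(features),
                 feature_names = colnames(features)),
            class = "ctc_classifier")
}

#' Predict hard labels
#'
#' @param model A [train_classifier()] handle.
#' @param features Numeric matrix with the training feature width.
#' @return Integer vector of 0/1 labels (empty input gives an empty
#'   vector).
#' @export
predict_labels <- function(model, features) {
  stopifnot(inherits(model, "ctc_classifier"))
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(integer(0))
  if (ncol(features) != model$p)
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(features), model$p), call. = FALSE)
  colnames(features) <- model$feature_names
  pred <- switch(model$spec$kind,
    # the explicit seed pins tree-vote tie-breaking, making prediction a
    # pure function of (model, features)
    random_forest = stats::predict(model$fit, data = features,
                                   num.threads = 1L,
                                   seed = model$spec$seed)$predictions,
    svm_rbf = kernlab::predict(model$fit, features)
  )
  as.integer(as.character(pred))
}

#' Score predictions against a reference labeling
#'
#' Confusion counts and the three performance measures:
#' accuracy (TP+TN)/(TP+FP+TN+FN), precision TP/(TP+FP) and recall
#' TP/(TP+FN). Precision (recall) is `NA` when no positives are predicted
#' (present).
#'
#' @param predictions,reference Binary vectors of equal length.
#' @return A list of class `performance_score` with `confusion` (named
#'   vector TP/FP/TN/FN), `accuracy`, `precision`, `recall`, `n`.
#' @export
score_predictions <- function(predictions, reference) {
  if (length(predictions) != length(reference))
    stop("predictions and reference differ in length", call. = FALSE)
  assert_binary(predictions, "predictions")
  assert_binary(reference, "reference labels")
  tp <- sum(predictions == 1 & reference == 1)
  fp <- sum(predictions == 1 & reference == 0)
  tn <- sum(predictions == 0 & reference == 0)
  fn <- sum(predictions == 0 & reference == 1)
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    accuracy = (tp + tn) / length(predictions),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    n = length(predictions)),
    class = "performance_score")
}

#' @export
print.performance_score <- function(x, ...) {
  cat(sprintf("n = %d | TP %d FP %d TN %d FN %d\n", x$n,
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("Acc %.3f  Pre %.3f  Rec %.3f\n",
              x$accuracy, x$precision, x$recall))
  invisible(x)
}

# Pool a list of confusion counts and score them.
pool_scores <- function(scores) {
  conf <- Reduce(`+`, lapply(scores, `[[`, "confusion"))
  tp <- conf["TP"]; fp <- conf["FP"]; tn <- conf["TN"]; fn <- conf["FN"]
  list(confusion = conf,
       accuracy = unname((tp + tn) / sum(conf)),
       precision = unname(if (tp + fp == 0) NA_real_ else tp / (tp + fp)),
       recall = unname(if (tp + fn == 0) NA_real_ else tp / (tp + fn)))
}
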