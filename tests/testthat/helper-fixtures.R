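# Shared fixtures, all generated in code.

# Annotation matrix from explicit columns.
ann_from_cols <- function(...) {
  annotation_matrix(cbind(...))
}

# Random binary annotation panel.
random_ann <- function(n, m, seed, p = 0.5) {
  withr::with_seed(seed, {
    annotation_matrix(matrix(rbinom(n * m, 1, p), n, m,
                             dimnames = list(NULL, paste0("O", seq_len(m)))))
  })
}

# Two well-separated 2-D Gaussian clusters: features informative by
# construction, labels = cluster id.
separable_features <- function(n, seed, gap = 4) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.5)
    x <- cbind(rnorm(n, gap * y), rnorm(n, -gap * y))
    colnames(x) <- c("f1", "f2")
    list(features = x, labels = y)
  })
}

# Uniform grey test cutout.
grey_cutout <- function(side = 60, value = 0.5, pixel_area = 1.0) {
  cutout(array(value, dim = c(side, side, 3)), pixel_area, "grey")
}

# Dense direct 2-D convolution with replicated borders: independent
# oracle for gaussian_smooth().
dense_convolve <- function(img, kernel) {
  n <- nrow(img)
  r <- (nrow(kernel) - 1) / 2
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), n)
      jj <- min(max(j + dj, 1), n)
      acc <- acc + img[ii, jj] * kernel[di + r + 1, dj + r + 1]
    }
    out[i, j] <- acc
  }
  out
}

# Standard classifier pair used throughout the experiment tests.
default_specs <- function(seed = 1) {
  list(RF = classifier_spec("random_forest", seed = seed),
       SVM = classifier_spec("svm_rbf"))
}
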