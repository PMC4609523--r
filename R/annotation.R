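#' Construct an annotation matrix
#'
#' Container for a multi-observer binary annotation of image cutouts:
#' one row per data point, one column per observer, entries 1 (CTC) or
#' 0 (no CTC). All interobserver statistics in the package operate on
#' this object.
#'
#' @param labels Numeric or integer matrix with entries in \{0, 1\};
#'   rows are data points, columns are observers. No missing values.
#' @param observer_ids Character vector of unique observer identifiers;
#'   defaults to `colnames(labels)` or `V1..VM`.
#' @param cutout_ids Optional character vector keying rows to image
#'   cutouts; defaults to `row names` or `cutout_0001..`.
#'
#' @return An object of class `annotation_matrix`: a list with elements
#'   `labels` (integer matrix), `observer_ids`, `cutout_ids`, `N` (number
#'   of data points) and `M` (number of observers).
#' @export
annotation_matrix <- function(labels, observer_ids = NULL, cutout_ids = NULL) {
  labels <- as.matrix(labels)
  if (nrow(labels) < 1L) stop("need at least one data point", call. = FALSE)
  if (ncol(labels) < 2L) stop("need at least two observers", call. = FALSE)
  assert_binary(labels, "annotation entries")
  storage.mode(labels) <- "integer"
  if (is.null(observer_ids)) {
    observer_ids <- colnames(labels)
    if (is.null(observer_ids)) observer_ids <- paste0("V", seq_len(ncol(labels)))
  }
  observer_ids <- as.character(observer_ids)
  if (length(observer_ids) != ncol(labels))
    stop("observer_ids length must match number of columns", call. = FALSE)
  if (anyDuplicated(observer_ids))
    stop("observer_ids must be unique", call. = FALSE)
  if (is.null(cutout_ids)) {
    cutout_ids <- rownames(labels)
    if (is.null(cutout_ids))
      cutout_ids <- sprintf("cutout_%04d", seq_len(nrow(labels)))
  }
  dimnames(labels) <- list(cutout_ids, observer_ids)
  structure(
    list(labels = labels, observer_ids = observer_ids,
         cutout_ids = as.character(cutout_ids),
         N = nrow(labels), M = ncol(labels)),
    class = "annotation_matrix"
  )
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation_matrix: %d data points x %d observers\n", x$N, x$M))
  cat("observers:", paste(x$observer_ids, collapse = ", "), "\n")
  cat("CTC votes per observer:",
      paste(colSums(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an annotation matrix as CSV
#'
#' The CSV layout is one header row of observer identifiers, one row per
#' cutout, cells in \{0, 1\}; an optional leading `cutout_id` column keys
#' rows to image files.
#'
#' @param path File path.
#' @return `read_annotation_matrix()` returns an [annotation_matrix()].
#' @export
read_annotation_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cutout_ids <- NULL
  if ("cutout_id" %in% names(df)) {
    cutout_ids <- as.character(df$cutout_id)
    df <- df[setdiff(names(df), "cutout_id")]
  }
  annotation_matrix(as.matrix(df), observer_ids = names(df),
                    cutout_ids = cutout_ids)
}

#' @param ann An [annotation_matrix()].
#' @rdname read_annotation_matrix
#' @export
write_annotation_matrix <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_matrix"))
  df <- data.frame(cutout_id = ann$cutout_ids, ann$labels,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise agreement between two observers
#'
#' The agreement between observers A and B over N data points is
#' \deqn{P_{Agr}(A,B) = 1 - \frac{1}{N}\sum_{i=1}^{N} |A_i - B_i|,}
#' i.e. one minus the normalized Hamming distance between their binary
#' label vectors: 1 for identical annotations, 0 for total disagreement.
#'
#' @param a,b Binary vectors of equal length.
#' @return A real number in \[0, 1\].
#' @export
#' @examples
#' pairwise_agreement(c(1, 1, 0, 0), c(1, 0, 0, 1))  # 0.5
pairwise_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  assert_binary(a, "labels")
  assert_binary(b, "labels")
  1 - mean(abs(a - b))
}

#' Agreement matrix across all observer pairs
#'
#' @param ann An [annotation_matrix()].
#' @return Symmetric M x M numeric matrix of pairwise agreements with
#'   unit diagonal, dimnames set to the observer identifiers.
#' @export
agreement_matrix <- function(ann) {
  stopifnot(inherits(ann, "annotation_matrix"))
  M <- ann$M
  vals <- diag(1, M)
  for (a in seq_len(M - 1L)) {
    for (b in seq.int(a + 1L, M)) {
      p <- pairwise_agreement(ann$labels[, a], ann$labels[, b])
      vals[a, b] <- vals[b, a] <- p
    }
  }
  dimnames(vals) <- list(ann$observer_ids, ann$observer_ids)
  vals
}

# Off-diagonal agreements, each unordered pair once (M*(M-1)/2 values).
offdiagonal_agreements <- function(ann) {
  am <- agreement_matrix(ann)
  am[upper.tri(am)]
}

#' Per-observer summary statistics
#'
#' For each observer A: the number of CTC labels, the mean agreement with
#' the other M - 1 observers
#' \deqn{P_{Agr}(A) = \frac{1}{M-1}\sum_{B \ne A} P_{Agr}(A,B),}
#' the signed mean difference in found CTCs
#' \deqn{\Delta CTC(A) = \frac{1}{M-1}\sum_{B \ne A} (N_{CTC}(A) - N_{CTC}(B)),}
#' and the standard error of the M - 1 pairwise agreements (sample SD
#' divided by `sqrt(M - 1)`).
#'
#' `delta_ctc` is signed: conservative observers (few CTC calls) get
#' negative values. Summed over all observers it is exactly zero.
#'
#' @param ann An [annotation_matrix()].
#' @return A data frame with one row per observer and columns
#'   `observer_id`, `n_ctc`, `mean_agreement`, `delta_ctc`, `se_agreement`.
#' @export
observer_summaries <- function(ann) {
  stopifnot(inherits(ann, "annotation_matrix"))
  if (ann$M < 2L) stop("need at least two observers", call. = FALSE)
  am <- agreement_matrix(ann)
  n_ctc <- colSums(ann$labels)
  M <- ann$M
  mean_agr <- se_agr <- delta <- numeric(M)
  for (a in seq_len(M)) {
    partners <- am[a, -a]
    mean_agr[a] <- mean(partners)
    se_agr[a] <- stats::sd(partners) / sqrt(M - 1L)
    delta[a] <- mean(n_ctc[a] - n_ctc[-a])
  }
  data.frame(observer_id = ann$observer_ids, n_ctc = as.integer(n_ctc),
             mean_agreement = mean_agr, delta_ctc = delta,
             se_agreement = se_agr, row.names = NULL)
}

#' Summary statistics of per-observer CTC counts
#'
#' Mean and median of the counts, plus the consecutive gaps in the
#' ascending-sorted counts, returned in descending gap order with the
#' flanking observer identifiers. The median uses the standard
#' convention (midpoint of the two central order statistics for even
#' length).
#'
#' @param counts Vector of nonnegative integer CTC counts.
#' @param ids Optional observer identifiers (defaults to `names(counts)`).
#' @return A list with `mean`, `median` and `sorted_gaps` (a data frame
#'   with columns `gap`, `from_id`, `from_count`, `to_id`, `to_count`).
#' @export
count_statistics <- function(counts, ids = names(counts)) {
  if (length(counts) == 0L) stop("empty count vector", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (is.null(ids)) ids <- paste0("obs", seq_along(counts))
  ord <- order(counts)
  sc <- counts[ord]
  sid <- ids[ord]
  if (length(counts) > 1L) {
    gaps <- diff(sc)
    g <- data.frame(gap = as.numeric(gaps),
                    from_id = sid[-length(sid)], from_count = sc[-length(sc)],
                    to_id = sid[-1L], to_count = sc[-1L],
                    row.names = NULL, stringsAsFactors = FALSE)
    g <- g[order(-g$gap), , drop = FALSE]
    rownames(g) <- NULL
  } else {
    g <- data.frame(gap = numeric(0), from_id = character(0),
                    from_count = numeric(0), to_id = character(0),
                    to_count = numeric(0))
  }
  list(mean = mean(counts), median = stats::median(counts), sorted_gaps = g)
}

#' Bernoulli model of observer agreement
#'
#' Under the assumption that every observer agrees with the (latent) label
#' of every cutout independently with the same probability p, two
#' observers agree with probability \eqn{P(A=B) = p^2 + (1-p)^2}; keeping
#' the dominant concordant term the paper-level approximation is
#' \eqn{P(A=B) = p^2}, so \eqn{p = \sqrt{P(A=B)}} and the expected number
#' of unanimous cutouts out of N is \eqn{N p^M}.
#'
#' The empirical mean pairwise agreement is the mean over the
#' M(M-1)/2 unordered observer pairs.
#'
#' @param ann An [annotation_matrix()].
#' @return A list with `mean_pairwise_agreement`, `p`
#'   (`sqrt(mean_pairwise_agreement)`), `expected_unanimous` (`N * p^M`),
#'   `N` and `M`.
#' @export
bernoulli_estimate <- function(ann) {
  stopifnot(inherits(ann, "annotation_matrix"))
  m <- mean(offdiagonal_agreements(ann))
  p <- sqrt(m)
  list(mean_pairwise_agreement = m, p = p,
       expected_unanimous = ann$N * p^ann$M, N = ann$N, M = ann$M)
}

#' One-sample t-test of pairwise agreements
#'
#' Two-sided one-sample Student's t-test of the observed pairwise
#' agreements against a hypothesized mean agreement (e.g. the agreement
#' implied by the observed number of unanimous cutouts).
#'
#' @param agreements Numeric vector (at least two values, nonzero
#'   variance).
#' @param hypothesized_mean The agreement under the null hypothesis.
#' @return A list with `t_statistic`, `p_value` and `df`.
#' @export
agreement_ttest <- function(agreements, hypothesized_mean) {
  if (length(agreements) < 2L)
    stop("need at least two agreement values", call. = FALSE)
  if (stats::sd(agreements) == 0)
    stop("agreements have zero variance; t-test degenerate", call. = FALSE)
  tt <- stats::t.test(agreements, mu = hypothesized_mean,
                      alternative = "two.sided")
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Published per-observer CTC counts
#'
#' The per-observer CTC counts of the eleven-observer annotation study
#' the package models (617 cutouts; consensus subset of 502), used as
#' input data for the count summary statistics. The two observers with a
#' conservative, false-positive-avoiding bias are flagged.
#'
#' @return A data frame with columns `observer_id`, `n_ctc_all`,
#'   `n_ctc_consensus`, `conservative`.
#' @export
ctc_reference_counts <- function() {
  data.frame(
    observer_id = c("SD", "MP", "TL", "ST", "MB", "BH", "MTF", "CMS",
                    "SB", "JP", "RH"),
    n_ctc_all = c(307L, 281L, 303L, 354L, 223L, 327L, 221L, 347L,
                  318L, 330L, 294L),
    n_ctc_consensus = c(244L, 244L, 248L, 258L, 206L, 257L, 210L, 260L,
                        255L, 250L, 245L),
    conservative = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                     FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}
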