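#' Consensus limit under a fair-coin binomial null
#'
#' The consensus limit c for n observers is the smallest number of
#' concordant votes whose one-sided tail probability under random
#' annotation, \eqn{P(X \ge c)} with \eqn{X \sim Binomial(n, 1/2)}, falls
#' below `alpha`. A cutout on which at least c observers agree (in either
#' direction) is then unlikely to have reached that concordance by
#' chance.
#'
#' @param n_observers Number of observers (>= 2).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The integer consensus limit, or `NA_integer_` if no c <= n
#'   satisfies the tail condition (consensus unattainable at this alpha).
#' @export
#' @examples
#' consensus_limit(11)  # 9
#' consensus_limit(5)   # 5
#' consensus_limit(3)   # NA: even unanimity has tail 1/8 >= 0.05
consensus_limit <- function(n_observers, alpha = 0.05) {
  n_observers <- as.integer(n_observers)
  if (is.na(n_observers) || n_observers < 2L)
    stop("n_observers must be an integer >= 2", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  candidates <- seq.int(floor(n_observers / 2) + 1L, n_observers)
  for (c in candidates) {
    tail <- stats::pbinom(c - 1L, n_observers, 0.5, lower.tail = FALSE)
    if (tail < alpha) return(as.integer(c))
  }
  NA_integer_
}

#' Consensus configuration
#'
#' Bundles the observer count, significance level and the resulting
#' consensus limit; errors if no consensus limit exists at this alpha.
#'
#' @inheritParams consensus_limit
#' @return A list of class `consensus_config` with `n_observers`,
#'   `alpha`, `c`.
#' @export
consensus_config <- function(n_observers, alpha = 0.05) {
  c <- consensus_limit(n_observers, alpha)
  if (is.na(c))
    stop("no consensus limit exists for ", n_observers,
         " observers at alpha = ", alpha, call. = FALSE)
  structure(list(n_observers = as.integer(n_observers), alpha = alpha,
                 c = c),
            class = "consensus_config")
}

#' Partition data points by consensus status
#'
#' Splits the data points of an annotation matrix into strata: the
#' consensus set (at least c observers agree, in either direction), the
#' total-consensus set (all observers agree, treated as ground truth,
#' GT), and the non-unanimous remainder (probGT), which only admits
#' probabilistic annotation.
#'
#' @param ann An [annotation_matrix()].
#' @param config A [consensus_config()] with `n_observers == ann$M`.
#' @return An object of class `consensus_partition`: a list with
#'   `consensus_mask`, `total_consensus_mask` (logical, length N),
#'   `consensus_labels` (integer, `NA` where no consensus), `votes`
#'   (CTC votes per row), `gt_indices`, `probgt_indices`, `config`.
#' @export
build_partition <- function(ann, config) {
  stopifnot(inherits(ann, "annotation_matrix"),
            inherits(config, "consensus_config"))
  if (config$n_observers != ann$M)
    stop("config observer count does not match annotation matrix",
         call. = FALSE)
  votes <- unname(rowSums(ann$labels))
  M <- ann$M
  c <- config$c
  consensus_mask <- votes >= c | (M - votes) >= c
  total_mask <- votes == M | votes == 0L
  labels <- rep(NA_integer_, ann$N)
  labels[consensus_mask] <- as.integer(votes[consensus_mask] >= c)
  structure(
    list(consensus_mask = consensus_mask,
         total_consensus_mask = total_mask,
         consensus_labels = labels,
         votes = as.integer(votes),
         gt_indices = which(total_mask),
         probgt_indices = which(!total_mask),
         config = config),
    class = "consensus_partition"
  )
}

#' @export
print.consensus_partition <- function(x, ...) {
  n <- length(x$consensus_mask)
  cat(sprintf("consensus_partition over %d points (c = %d of %d observers)\n",
              n, x$config$c, x$config$n_observers))
  cat(sprintf("  consensus reached: %d (%.1f%%)\n",
              sum(x$consensus_mask), 100 * mean(x$consensus_mask)))
  cat(sprintf("  total consensus (GT): %d; probabilistic (probGT): %d\n",
              length(x$gt_indices), length(x$probgt_indices)))
  invisible(x)
}

#' Export a consensus partition as a data frame
#'
#' One row per cutout: vote count, consensus status, consensus label and
#' GT/probGT stratum; suitable for writing to CSV.
#'
#' @param partition A [build_partition()] result.
#' @param ann The matching [annotation_matrix()].
#' @return A data frame with columns `cutout_id`, `n_votes_ctc`,
#'   `consensus`, `stratum`, `consensus_label`.
#' @export
partition_table <- function(partition, ann) {
  stopifnot(inherits(partition, "consensus_partition"))
  data.frame(
    cutout_id = ann$cutout_ids,
    n_votes_ctc = partition$votes,
    consensus = ifelse(partition$consensus_mask, "yes", "none"),
    stratum = ifelse(partition$total_consensus_mask, "GT", "probGT"),
    consensus_label = partition$consensus_labels,
    stringsAsFactors = FALSE
  )
}

#' Sample a probabilistic annotation
#'
#' For each requested data point a single observer is chosen uniformly at
#' random and that observer's label is returned. Unanimous rows always
#' yield the unanimous label; non-unanimous rows yield label 1 with
#' probability equal to the row's CTC vote fraction. Reproducible under
#' the seed.
#'
#' @param ann An [annotation_matrix()].
#' @param indices Nonempty integer vector of row indices.
#' @param seed Integer RNG seed.
#' @return Integer vector of labels over `indices` (in their order).
#' @export
sample_probabilistic_annotation <- function(ann, indices, seed) {
  stopifnot(inherits(ann, "annotation_matrix"))
  if (length(indices) == 0L) stop("empty index set", call. = FALSE)
  if (any(indices < 1L | indices > ann$N))
    stop("indices out of range", call. = FALSE)
  withr::with_seed(seed, {
    picks <- sample.int(ann$M, length(indices), replace = TRUE)
    ann$labels[cbind(indices, picks)]
  })
}

#' Expected label changes between two probabilistic annotations
#'
#' With q_i the CTC vote fraction at point i, two independent
#' probabilistic annotations differ at i with probability
#' \eqn{2 q_i (1 - q_i)}; the expected Hamming distance over an index set
#' is the sum of those terms. Unanimous points never change.
#'
#' @param ann An [annotation_matrix()].
#' @param indices Integer vector of row indices (defaults to all rows).
#' @return Expected number of label changes (a nonnegative real).
#' @export
expected_label_changes <- function(ann, indices = seq_len(ann$N)) {
  stopifnot(inherits(ann, "annotation_matrix"))
  if (length(indices) == 0L) return(0)
  q <- rowSums(ann$labels[indices, , drop = FALSE]) / ann$M
  sum(2 * q * (1 - q))
}
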