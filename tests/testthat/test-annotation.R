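test_that("pairwise agreement matches its definition and edge cases", {
  expect_equal(pairwise_agreement(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(pairwise_agreement(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(pairwise_agreement(c(1, 1, 0, 0), c(1, 0, 0, 1)), 0.5)
  expect_error(pairwise_agreement(c(1, 0), c(1, 0, 1)), "length")
  expect_error(pairwise_agreement(c(1, 2), c(1, 0)), "binary")
})

test_that("pairwise agreement equals 1 - Hamming/N on random vectors", {
  withr::with_seed(42, {
    for (k in 1:20) {
      n <- sample(3:40, 1)
      a <- rbinom(n, 1, 0.5)
      b <- rbinom(n, 1, 0.5)
      hamming <- sum(a != b)  # brute-force count
      expect_equal(pairwise_agreement(a, b), 1 - hamming / n)
      expect_equal(pairwise_agreement(a, b), pairwise_agreement(b, a))
      expect_gte(pairwise_agreement(a, b), 0)
      expect_lte(pairwise_agreement(a, b), 1)
    }
  })
})

test_that("agreement matrix is symmetric with unit diagonal", {
  a <- c(1, 0, 1, 0)
  ann <- ann_from_cols(A = a, B = a)
  expect_equal(unname(agreement_matrix(ann)), matrix(1, 2, 2))

  ann3 <- ann_from_cols(A = a, B = 1 - a, C = c(1, 1, 0, 0))
  am <- agreement_matrix(ann3)
  expect_equal(am["A", "B"], 0)
  expect_equal(am, t(am))
  expect_equal(unname(diag(am)), rep(1, 3))

  r <- random_ann(25, 5, seed = 7)
  am <- agreement_matrix(r)
  expect_equal(am, t(am))
  expect_true(all(am >= 0 & am <= 1))
})

test_that("observer summaries match a brute-force pair loop", {
  ann <- random_ann(10, 4, seed = 3)
  # extreme observers: one all-positive, one all-negative
  labs <- ann$labels
  labs[, 1] <- 1L
  labs[, 2] <- 0L
  ann <- annotation_matrix(labs)
  s <- observer_summaries(ann)

  # brute-force oracle over all ordered pairs
  M <- ann$M
  for (a in seq_len(M)) {
    agr <- del <- c()
    for (b in setdiff(seq_len(M), a)) {
      agr <- c(agr, 1 - mean(abs(ann$labels[, a] - ann$labels[, b])))
      del <- c(del, sum(ann$labels[, a]) - sum(ann$labels[, b]))
    }
    expect_equal(s$mean_agreement[a], mean(agr))
    expect_equal(s$delta_ctc[a], mean(del))
    expect_equal(s$se_agreement[a], sd(agr) / sqrt(M - 1))
  }
  expect_equal(s$n_ctc, unname(colSums(ann$labels)))
})

test_that("delta_ctc sums to zero and vanishes for identical observers", {
  for (seed in 1:5) {
    ann <- random_ann(30, 6, seed = seed)
    expect_equal(sum(observer_summaries(ann)$delta_ctc), 0)
  }
  a <- c(1, 0, 1, 1, 0)
  ident <- ann_from_cols(A = a, B = a, C = a)
  s <- observer_summaries(ident)
  expect_equal(s$delta_ctc, rep(0, 3))
  expect_equal(s$mean_agreement, rep(1, 3))
})

test_that("count statistics report mean, median and ordered gaps", {
  cs <- count_statistics(c(a = 5, b = 5, c = 5))
  expect_equal(cs$mean, 5)
  expect_equal(cs$median, 5)
  expect_equal(cs$sorted_gaps$gap, c(0, 0))

  cs <- count_statistics(c(x = 10, y = 2, z = 7))
  expect_equal(cs$median, 7)
  expect_equal(cs$sorted_gaps$gap[1], 5)  # 2 -> 7
  expect_equal(cs$sorted_gaps$from_id[1], "y")
  expect_equal(cs$sorted_gaps$to_id[1], "z")
  expect_error(count_statistics(numeric(0)), "empty")
})

test_that("Bernoulli estimate follows the agreement model and is monotone", {
  a <- rep(1, 10)
  ann <- ann_from_cols(A = a, B = a, C = a)
  be <- bernoulli_estimate(ann)
  expect_equal(be$mean_pairwise_agreement, 1)
  expect_equal(be$p, 1)
  expect_equal(be$expected_unanimous, ann$N)

  # flipping progressively more single-observer entries lowers agreement
  # and with it the expected number of unanimous cutouts
  prev <- Inf
  labs <- matrix(1L, 20, 4)
  for (k in c(2, 5, 9)) {
    l2 <- labs
    l2[seq_len(k), 1] <- 0L
    be <- bernoulli_estimate(annotation_matrix(l2))
    expect_lt(be$expected_unanimous, prev)
    expect_equal(be$p, sqrt(be$mean_pairwise_agreement))
    expect_equal(be$expected_unanimous, be$N * be$p^be$M)
    prev <- be$expected_unanimous
  }
})

test_that("agreement t-test handles exact and stochastic cases", {
  r <- agreement_ttest(c(0.8, 0.85, 0.9), 0.85)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(agreement_ttest(c(0.8, 0.9), 0.85)$t_statistic, 0)
  expect_error(agreement_ttest(c(0.8, 0.8), 0.85), "variance")

  # panels like the measured ones are significantly below the
  # unanimity-implied agreement in essentially every replicate
  hits <- withr::with_seed(99, {
    sum(vapply(1:100, function(i) {
      vals <- rnorm(55, 0.85, 0.03)
      agreement_ttest(vals, 0.91)$p_value < 1e-6
    }, logical(1)))
  })
  expect_gte(hits, 99)
})

test_that("annotation matrix validates input and round-trips CSV", {
  expect_error(annotation_matrix(matrix(c(0, 2), 1, 2)), "binary")
  expect_error(annotation_matrix(matrix(0, 3, 1)), "two observers")
  expect_error(annotation_matrix(matrix(1, 2, 2),
                                 observer_ids = c("A", "A")), "unique")
  ann <- random_ann(12, 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotation_matrix(ann, path)
  back <- read_annotation_matrix(path)
  expect_equal(back$labels, ann$labels)
  expect_equal(back$observer_ids, ann$observer_ids)
})
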