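test_that("generated cutouts encode the staining rules", {
  # unambiguous CTC: strong blue and green, red at background level
  sp <- scene_spec(1, 0, pixel_area = 1.0, seed = 2)
  co <- generate_cutout(sp)
  expect_gte(max(co$pixels[, , 3]), 0.8)  # blue nucleus
  expect_gte(max(co$pixels[, , 2]), 0.8)  # green EpCAM/cytokeratin
  # no true CD45 signal: red is only background (with illumination
  # variation) plus green->red spectral crosstalk, well below the
  # leukocyte staining level
  expect_lte(max(co$pixels[, , 1]), 0.45)

  # red-positive leukocyte scene
  co0 <- generate_cutout(scene_spec(0, 0.2, seed = 3,
                                    non_ctc_mode = "leukocyte"))
  expect_gte(max(co0$pixels[, , 1]), 0.5)

  # determinism
  expect_identical(generate_cutout(sp)$pixels, generate_cutout(sp)$pixels)

  # raster side: physical crop side plus margin, for all magnifications
  for (pa in c(1.0, 0.5, 0.25)) {
    co <- generate_cutout(scene_spec(1, 0.5, pixel_area = pa, seed = 4))
    expect_equal(dim(co$pixels)[1], crop_side(2500, pa) + 10L)
  }
})

test_that("simulated observers reproduce truth when scenes are clear and
           diverge as specified when they are not", {
  neutral <- observer_profile("N")
  cons <- observer_profile("C", conservative = TRUE)
  clear1 <- scene_spec(1, 0, seed = 1)
  clear0 <- scene_spec(0, 0, seed = 1)
  for (s in 1:25) {
    expect_identical(simulate_observer(neutral, clear1, s), 1L)
    expect_identical(simulate_observer(cons, clear1, s), 1L)
    expect_identical(simulate_observer(neutral, clear0, s), 0L)
  }
  hard1 <- scene_spec(1, 1, seed = 1)
  cons_labels <- vapply(1:200, function(s)
    simulate_observer(cons, hard1, s), integer(1))
  expect_gte(mean(cons_labels == 0L), 0.9)
  neut_labels <- vapply(1:400, function(s)
    simulate_observer(neutral, hard1, s), integer(1))
  expect_lt(abs(mean(neut_labels) - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("panels are reproducible and unanimous when scenes are trivial", {
  profiles <- default_observer_panel()
  easy_mix <- difficulty_mixture(0, clear_shape = c(1, 1e6))
  pan <- generate_panel(60, profiles, easy_mix, seed = 5, images = FALSE)
  expect_true(all(pan$ann$labels == pan$truth))

  p1 <- generate_panel(30, profiles, difficulty_mixture(0.3), seed = 6,
                       images = FALSE)
  p2 <- generate_panel(30, profiles, difficulty_mixture(0.3), seed = 6,
                       images = FALSE)
  expect_identical(p1$ann$labels, p2$ann$labels)
  expect_identical(p1$truth, p2$truth)
})

test_that("panel agreement decreases with the ambiguous mass", {
  profiles <- default_observer_panel()
  agr <- vapply(c(0.1, 0.4, 0.7), function(w) {
    pan <- generate_panel(800, profiles, difficulty_mixture(w), seed = 7,
                          images = FALSE)
    mean(agreement_matrix(pan$ann)[upper.tri(diag(11))])
  }, numeric(1))
  expect_true(all(diff(agr) < 0))
})

test_that("conservative profiles find fewer CTCs and agree less", {
  pan <- generate_panel(1000, default_observer_panel(),
                        difficulty_mixture(0.5), seed = 8, images = FALSE)
  s <- observer_summaries(pan$ann)
  cons <- grepl("^C", s$observer_id)
  expect_lt(max(s$n_ctc[cons]), min(s$n_ctc[!cons]))
  expect_lt(max(s$mean_agreement[cons]), min(s$mean_agreement[!cons]))
})

test_that("generated cutouts round-trip through preprocessing and support a
           classifier at difficulty zero", {
  easy_mix <- difficulty_mixture(0, clear_shape = c(1, 1e6))
  pan <- generate_panel(260, default_observer_panel(), easy_mix, seed = 9)
  feats <- preprocess_batch(pan$cutouts)
  expect_equal(dim(feats), c(260, 5000))
  m <- train_classifier(classifier_spec("random_forest", seed = 10),
                        feats[1:200, ], pan$truth[1:200])
  acc <- mean(predict_labels(m, feats[201:260, ]) == pan$truth[201:260])
  expect_gte(acc, 0.95)
})

test_that("calibration hits trivial targets and fails impossible ones", {
  # perfect agreement is achieved with zero ambiguous mass
  cal <- calibrate_difficulty(target_agreement = 1,
                              target_consensus_fraction = 1,
                              n_points = 250, n_replicates = 2, seed = 12)
  expect_equal(cal$mixture$ambiguous_mass, 0)

  # conservative-only panels cannot be maximally discordant
  cons_only <- lapply(1:7, function(i)
    observer_profile(paste0("C", i), conservative = TRUE))
  expect_error(
    calibrate_difficulty(target_agreement = 0.5,
                         target_consensus_fraction = 0.5,
                         profiles = cons_only, n_points = 250,
                         n_replicates = 2, seed = 13),
    class = "calibration_failure")
})
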