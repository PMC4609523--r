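test_that("crop side lengths reproduce the magnification triple", {
  expect_equal(crop_side(2500, c(0.25, 0.5, 1.0)), c(100L, 71L, 50L))
  co <- grey_cutout(side = 110, pixel_area = 0.25)
  expect_equal(dim(crop_to_region(co)$pixels), c(100, 100, 3))
  co <- grey_cutout(side = 80, pixel_area = 0.5)
  expect_equal(dim(crop_to_region(co)$pixels), c(71, 71, 3))
  co <- grey_cutout(side = 60, pixel_area = 1.0)
  expect_equal(dim(crop_to_region(co)$pixels), c(50, 50, 3))
  expect_error(crop_to_region(grey_cutout(side = 40, pixel_area = 1.0)),
               "exceeds")
})

test_that("gaussian smoothing preserves constants and sigma 0 is identity", {
  co <- grey_cutout(side = 30, value = 0.4)
  expect_equal(gaussian_smooth(co, 1)$pixels, co$pixels, tolerance = 1e-10)
  rnd <- withr::with_seed(4, {
    cutout(array(runif(30 * 30 * 3), c(30, 30, 3)), 1.0)
  })
  expect_identical(gaussian_smooth(rnd, 0)$pixels, rnd$pixels)
  expect_error(gaussian_smooth(co, -1), "nonnegative")
})

test_that("gaussian smoothing matches a dense-convolution oracle", {
  # unit impulse at the center
  px <- array(0, c(21, 21, 3))
  px[11, 11, ] <- 1
  co <- cutout(px, 1.0)
  sm <- gaussian_smooth(co, 1)
  k <- gaussian_kernel(1)
  expect_equal(sm$pixels[11, 11, 1], max(k), tolerance = 1e-8)

  # full-field comparison on a random image, all three channels
  rnd <- withr::with_seed(11, {
    cutout(array(runif(21 * 21 * 3), c(21, 21, 3)), 1.0)
  })
  sm <- gaussian_smooth(rnd, 1.3)
  k <- gaussian_kernel(1.3)
  for (ch in 1:3) {
    oracle <- dense_convolve(rnd$pixels[, , ch], k)
    expect_equal(sm$pixels[, , ch], oracle, tolerance = 1e-8)
  }
})

test_that("bilinear downsampling preserves constants, ramps and means", {
  co <- grey_cutout(side = 50, value = 0.3)
  expect_identical(downsample(co, 50)$pixels, co$pixels)

  co100 <- grey_cutout(side = 100, value = 0.3)
  down <- downsample(co100, 50)
  expect_equal(dim(down$pixels), c(50, 50, 3))
  expect_equal(down$pixels, array(0.3, c(50, 50, 3)), tolerance = 1e-10)

  # horizontal linear ramp keeps endpoints and slope
  ramp <- array(rep(seq(0, 1, length.out = 100), each = 100), c(100, 100, 3))
  dr <- downsample(cutout(ramp, 1.0), 50)
  expect_equal(dr$pixels[1, 1, 1], 0, tolerance = 0.02)
  expect_equal(dr$pixels[1, 50, 1], 1, tolerance = 0.02)
  expect_equal(mean(dr$pixels), mean(ramp), tolerance = 0.02)
  expect_error(downsample(co, 80), "upsampling")
})

test_that("hue/saturation conversion follows the hexcone formulas", {
  grey <- grey_cutout(side = 50, value = 0.7)
  v <- to_hue_saturation(grey)
  expect_equal(unname(v[2501:5000]), rep(0, 2500))  # achromatic: S = 0
  expect_equal(unname(v[1:2500]), rep(0, 2500))     # H defaults to 0

  red <- cutout(array(rep(c(1, 0, 0), each = 2500), c(50, 50, 3)), 1.0)
  v <- to_hue_saturation(red)
  expect_equal(unname(v[1:2500]), rep(0, 2500))
  expect_equal(unname(v[2501:5000]), rep(1, 2500))

  green <- cutout(array(rep(c(0, 1, 0), each = 2500), c(50, 50, 3)), 1.0)
  v <- to_hue_saturation(green)
  expect_equal(unname(v[1]), 1 / 3)
  expect_equal(unname(v[2501]), 1)

  expect_error(to_hue_saturation(grey_cutout(side = 30)), "expected")
})

test_that("feature layout is hue block then saturation block, row-major", {
  # a single distinctive pixel at raster position (row 1, col 2)
  px <- array(rep(c(0.5, 0.5, 0.5), each = 2500), c(50, 50, 3))
  px[1, 2, ] <- c(0, 1, 0)
  v <- to_hue_saturation(cutout(px, 1.0))
  expect_equal(unname(v[2]), 1 / 3)        # H block, row-major position 2
  expect_equal(unname(v[2500 + 2]), 1)     # S block, same position
  expect_equal(sum(v[2501:5000] > 0), 1)   # all other pixels achromatic
})

test_that("full pipeline yields a 5000-entry deterministic vector in [0,1]", {
  for (pa in c(1.0, 0.5, 0.25)) {
    co <- generate_cutout(scene_spec(1, 0.2, pixel_area = pa, seed = 3))
    v <- preprocess(co)
    expect_length(v, 5000)
    expect_true(all(v >= 0 & v <= 1))
    expect_identical(v, preprocess(co))
  }
  # non-default geometry: length 2 * target_side^2
  cfg <- preprocess_config(target_side = 20)
  expect_length(preprocess(grey_cutout(side = 60), cfg), 800)
})

test_that("pipeline is invariant to a global intensity rescaling", {
  co <- generate_cutout(scene_spec(1, 0.1, seed = 9))
  dim3 <- dim(co$pixels)
  dark <- cutout(co$pixels * 0.5, co$pixel_area, co$cutout_id)
  v1 <- preprocess(co)
  v2 <- preprocess(dark)
  expect_equal(v1, v2, tolerance = 1e-6)
})
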