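test_that("length models are calibrated and respect their support", {
  lm <- length_model_unmasked()        # mean 225 um on [100, 550]
  x <- fibermag:::with_seed(1, sample_lengths(lm, 5000))
  expect_true(all(x >= 100 & x <= 550))
  expect_equal(mean(x), 225, tolerance = 0.02)
  # analytic truncated mean equals the target exactly
  expect_equal(fibermag:::.trunc_lnorm_mean(lm$meanlog, lm$sdlog, 100, 550),
               225, tolerance = 1e-8)
  lmm <- length_model_masked(90, 15)
  y <- fibermag:::with_seed(2, sample_lengths(lmm, 5000))
  expect_true(all(y >= 45 & y <= 135))
  expect_equal(mean(y), 90, tolerance = 0.02)
})

test_that("fiber scenes are deterministic and carry exact truth geometry", {
  sc1 <- small_fiber_scene(seed = 42)
  sc2 <- small_fiber_scene(seed = 42)
  expect_identical(sc1$image, sc2$image)
  expect_identical(sc1$fibers, sc2$fibers)
  # truth-mask consistency: re-rasterizing the truth reproduces the support
  re <- fibermag:::rasterize_fibers(sc1$fibers, sc1$spec$image_shape,
                                    sc1$spec$pixel_size)
  expect_identical(re > 0, sc1$support)
  # endpoint geometry is self-consistent
  f <- sc1$fibers
  expect_equal(sqrt((f$x1 - f$x0)^2 + (f$y1 - f$y0)^2) * sc1$spec$pixel_size,
               f$length_um, tolerance = 1e-9)
})

test_that("orientation statistics follow the requested concentration", {
  # kappa = 0: truth angles circular-uniform (Rayleigh on doubled angles)
  sc <- generate_fiber_image(fiber_field_spec(
    image_shape = c(900, 900), n_fibers = 300,
    length_model = length_model_masked(60), orientation_kappa = 0, seed = 5))
  expect_gt(rayleigh_p(2 * sc$fibers$angle * pi / 180), 0.01)
  # kappa -> infinity: angles pile on the mean axis
  sc2 <- generate_fiber_image(fiber_field_spec(
    image_shape = c(900, 900), n_fibers = 100,
    length_model = length_model_masked(60), orientation_kappa = 1e6,
    mean_axis = 0, seed = 6))
  expect_true(all(axial_distance(sc2$fibers$angle, 0) < 0.1))
  # moment calibration: sample mean length within 3 se of the model mean
  sc3 <- generate_fiber_image(fiber_field_spec(
    image_shape = c(1400, 1400), n_fibers = 500,
    length_model = length_model_unmasked(), orientation_kappa = 2, seed = 7))
  se <- sd(sc3$fibers$length_um) / sqrt(500)
  expect_lt(abs(mean(sc3$fibers$length_um) - 225), 3 * se)
})

test_that("impossible fiber scenes raise parameter errors", {
  expect_error(fiber_field_spec(image_shape = c(256, 256),
                                length_model = length_model_unmasked()),
               "image too small")
  expect_error(fiber_field_spec(orientation_kappa = -1), "orientation_kappa")
  # overcrowded non-overlap packing names the density limit
  expect_error(generate_fiber_image(fiber_field_spec(
    image_shape = c(256, 256), n_fibers = 400,
    length_model = length_model_masked(40, 5), overlap = FALSE, seed = 1)),
    "non-overlapping")
})
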