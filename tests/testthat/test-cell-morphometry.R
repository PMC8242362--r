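test_that("per-cell orientations are recovered from tenocyte scenes", {
  sc <- generate_tenocyte_image(60, orientation_kappa = 4, aspect_ratio = 4,
                                seed = 8)
  cells <- segment_cells(sc$image, sc$pixel_size)
  expect_equal(nrow(cells), 60)
  near <- vapply(seq_len(nrow(cells)), function(i)
    which.min((sc$cells$cx - cells$cx[i])^2 + (sc$cells$cy - cells$cy[i])^2),
    integer(1))
  err <- axial_distance(cells$orientation, sc$cells$angle[near])
  expect_true(all(err < 5))
  expect_true(all(cells$aspect_ratio > 3))
  # 90 deg rotation shifts measured orientations by 90 (mod 180)
  rot <- t(sc$image)[nrow(sc$image):1, ]
  cells_rot <- segment_cells(rot, sc$pixel_size)
  h <- orientation_histogram(cells$orientation)
  h_rot <- orientation_histogram(cells_rot$orientation, reference_axis = 90)
  expect_equal(h_rot$counts, h$counts)
  # round cells are excluded from the orientation set
  rc <- generate_tenocyte_image(12, aspect_ratio = 1, seed = 9)
  cr <- segment_cells(rc$image, rc$pixel_size)
  expect_true(all(is.na(cr$orientation)))
})

test_that("FWHM follows the axial von Mises half-max oracle", {
  # degenerate: all angles equal -> minimal resolvable width (one bin)
  expect_equal(orientation_histogram(rep(0, 50))$fwhm, 10)
  # flat: uniform angles -> 180 by convention
  u <- seq(-89.9, 89.9, length.out = 720)
  expect_equal(orientation_histogram(u)$fwhm, 180)
  expect_error(orientation_histogram(1:5), "at least 10")
  # kappa = 4 sample: FWHM within one bin of the analytic half-max width
  a <- fibermag:::with_seed(3, sample_axial_angles(800, 0, 4))
  fw <- orientation_histogram(a)$fwhm
  expect_lt(abs(fw - axial_vm_fwhm_oracle(4)), 10)
  # oracle consistency at very large kappa: width collapses
  expect_lt(axial_vm_fwhm_oracle(200), 7)
})

test_that("angular stratification partitions mass as expected", {
  u <- seq(-89.99, 89.99, length.out = 3600)
  f <- angular_stratification(u)
  expect_equal(sum(f), 1)
  expect_equal(unname(f), rep(1 / 3, 3), tolerance = 0.01)
  expect_equal(unname(angular_stratification(45)), c(0, 1, 0))
  a <- fibermag:::with_seed(4, sample_axial_angles(2000, 0, 8))
  p <- axial_band_probability(8, 30)
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(angular_stratification(a)[["0-30"]] - p), 3 * se)
  # arbitrary reference axis
  expect_equal(unname(angular_stratification(c(50, 50), reference_axis = 50)),
               c(1, 0, 0))
})

test_that("viability counting matches the generated dead fraction", {
  for (f in c(0, 0.25, 1)) {
    v <- generate_viability_image(400, f, seed = 10 + round(100 * f))
    r <- viability(v$hoechst, v$pi, v$pixel_size)
    expect_lt(abs(r$n_total - 400) / 400, 0.03)
    expect_lt(abs(r$percent_dead - 100 * f), 3)
  }
  expect_error(viability(matrix(0, 64, 64), matrix(0, 64, 64)), "no nuclei")
})
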