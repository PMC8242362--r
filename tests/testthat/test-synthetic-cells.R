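test_that("tenocyte scenes place non-overlapping cells with recorded angles", {
  sc <- generate_tenocyte_image(60, orientation_kappa = 8, aspect_ratio = 4,
                                seed = 3)
  expect_equal(nrow(sc$cells), 60)
  expect_false(any(sc$cells$isotropic))
  # concentration: at kappa = 8 at least 70% of truth angles within 30 deg
  # (analytic mass is ~99%)
  expect_gte(mean(axial_distance(sc$cells$angle, 0) < 30), 0.7)
  # determinism
  sc2 <- generate_tenocyte_image(60, orientation_kappa = 8, aspect_ratio = 4,
                                 seed = 3)
  expect_identical(sc$image, sc2$image)
  # round cells are flagged isotropic with NA angles
  sc3 <- generate_tenocyte_image(10, aspect_ratio = 1, seed = 4)
  expect_true(all(sc3$cells$isotropic))
  expect_true(all(is.na(sc3$cells$angle)))
  # packing failure names the density limit
  expect_error(generate_tenocyte_image(4000, seed = 5,
                                       image_shape = c(256, 256)),
               "density")
})

test_that("viability scenes carry an exact dead count", {
  v0 <- generate_viability_image(50, 0, seed = 1)
  expect_equal(v0$n_dead, 0)
  expect_false(any(v0$nuclei$dead))
  # PI channel is pure background when nothing is dead
  expect_lt(max(v0$pi), 5 * 0.02 + 0.01)
  v1 <- generate_viability_image(50, 1, seed = 2)
  expect_true(all(v1$nuclei$dead))
  # round-half-even count
  v <- generate_viability_image(400, 0.5, seed = 3)
  expect_equal(v$n_dead, 200)
  expect_equal(sum(v$nuclei$dead), 200)
  expect_error(generate_viability_image(10, 1.5), "dead_fraction")
})
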