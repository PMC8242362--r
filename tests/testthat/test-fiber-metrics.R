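sinus_stripes <- function(n = 300, period = 10, along = "x") {
  v <- sin(2 * pi * (0:(n - 1)) / period)
  if (along == "x") matrix(rep(v, times = n), n, n)  # varies along rows
  else matrix(rep(v, each = n), n, n)                # varies along cols
}

test_that("anisotropy score separates parallel stripes from isotropic noise", {
  # stripes along 0 deg: intensity varies across rows only
  a <- anisotropy_score(sinus_stripes(along = "x"))
  expect_gte(a$score, 0.95)
  expect_lt(axial_distance(a$mean_orientation, 0), 2)
  a90 <- anisotropy_score(sinus_stripes(along = "y"))
  expect_gte(a90$score, 0.95)
  expect_lt(axial_distance(a90$mean_orientation, 90), 2)
  # isotropic filtered noise scores ~0
  nz <- fibermag:::with_seed(1,
    as.matrix(EBImage::gblur(matrix(rnorm(512^2), 512, 512), 2)))
  expect_lte(anisotropy_score(nz)$score, 0.05)
  # blank image has no usable gradients
  expect_error(anisotropy_score(matrix(0, 64, 64)), "undefined anisotropy")
})

test_that("anisotropy is rotation-equivariant and intensity-scale invariant", {
  sc <- small_fiber_scene(seed = 11, kappa = 4)
  a <- anisotropy_score(sc$image)
  # 90 deg rotation: transpose + flip rows maps angle t to t + 90 (mod 180)
  rot <- t(sc$image)[nrow(sc$image):1, ]
  a_rot <- anisotropy_score(rot)
  expect_equal(a_rot$score, a$score, tolerance = 1e-9)
  expect_lt(axial_distance(a_rot$mean_orientation, a$mean_orientation + 90),
            1e-6)
  a_sc <- anisotropy_score(sc$image * 3.7)
  expect_equal(a_sc$score, a$score, tolerance = 1e-12)
})

test_that("orientation map recovers stripe orientation and coherency", {
  m <- orientation_map(sinus_stripes(along = "x"), window_sigma = 4)
  inner <- m$coherency[50:250, 50:250] > 0.5
  expect_gt(mean(inner), 0.9)
  ori <- m$orientation[50:250, 50:250][inner[] == TRUE]
  expect_lt(median(axial_distance(ori, 0)), 2)
  # constant image: coherency 0 everywhere
  m0 <- orientation_map(matrix(1, 128, 128), window_sigma = 3)
  expect_equal(max(m0$coherency), 0)
  # two-region image: bimodal orientation histogram at 0 and 90
  img <- cbind(sinus_stripes(200, along = "x")[, 1:100],
               sinus_stripes(200, along = "y")[, 1:100])
  m2 <- orientation_map(img, window_sigma = 3)
  left <- m2$orientation[20:180, 20:80]
  right <- m2$orientation[20:180, 120:180]
  expect_lt(median(axial_distance(left, 0)), 5)
  expect_lt(median(axial_distance(right, 90)), 5)
  rgb <- orientation_rgb(m2)
  expect_equal(dim(rgb), c(200, 200, 3))
  expect_true(all(rgb >= 0 & rgb <= 1))
})

test_that("a single rod is measured to its true length and diameter", {
  img <- fibermag:::blank_image(c(400, 400))
  img <- fibermag:::draw_capsule(img, 50, 200, 350, 200, 4)  # 150 x 2 um
  m <- measure_fibers(img, 0.5)
  expect_equal(nrow(m), 1)
  expect_equal(m$length_um, 150, tolerance = 0.03)
  expect_equal(m$diameter_um, 2, tolerance = 0.15)
})

test_that("scene-level length recovery is unit-consistent", {
  sc <- small_fiber_scene(seed = 12, n = 40)
  m1 <- measure_fibers(sc$image, 0.5)
  expect_equal(mean(m1$length_um), mean(sc$fibers$length_um),
               tolerance = 0.1)
  # same geometry declared at 1.0 um/px must scale measurements in um
  m2 <- measure_fibers(sc$image, 1.0)
  expect_equal(mean(m2$length_um) / mean(m1$length_um), 2, tolerance = 0.05)
  # empty image: empty measurement set, not an error
  expect_message(m0 <- measure_fibers(matrix(0, 64, 64), 0.5), "no foreground")
  expect_equal(nrow(m0), 0)
})

test_that("entanglement fraction flags merged clumps and spares clean fields", {
  sc <- small_fiber_scene(seed = 13, n = 30)
  m <- measure_fibers(sc$image, 0.5)
  single <- median(m$length_um) * median(m$diameter_um)
  expect_equal(entanglement_fraction(m, single), 0)
  # everything merged into one blob: fraction 1
  blob <- fibermag:::blank_image(c(200, 200))
  for (y in seq(60, 140, by = 3))
    blob <- fibermag:::draw_capsule(blob, 40, y, 160, y + 10, 4)
  mb <- measure_fibers(blob, 0.5)
  expect_equal(entanglement_fraction(mb, single), 1)
  expect_error(entanglement_fraction(m[0, ], single), "zero total")
})
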