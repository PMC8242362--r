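# independent numeric oracles used across tests

# FWHM of the axial von Mises density exp(kappa * cos(2 theta)), degrees:
# closed-form half-max solve (independent of the histogram implementation)
axial_vm_fwhm_oracle <- function(kappa) {
  if (2 * kappa < log(2)) return(180)
  2 * (180 / pi) * 0.5 * acos(1 - log(2) / kappa)
}

# probability mass of the axial von Mises density within +/- half_width deg,
# by midpoint-rule summation (independent of stats::integrate)
axial_band_oracle <- function(kappa, half_width = 30) {
  th <- seq(-pi / 2, pi / 2, length.out = 20001)
  d <- exp(kappa * cos(2 * th))
  sum(d[abs(th) <= half_width * pi / 180]) / sum(d)
}

# Rayleigh test p-value for circular uniformity (angles in radians)
rayleigh_p <- function(theta) {
  n <- length(theta)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# brute-force nearest distance from a point to an ellipse boundary by
# dense parameter sampling (oracle for the bisection solver)
ellipse_distance_oracle <- function(px, py, center, semiaxes, rotation = 0) {
  t <- seq(0, 2 * pi, length.out = 20000)
  th <- rotation * pi / 180
  bx <- semiaxes[1] * cos(t); by <- semiaxes[2] * sin(t)
  x <- center[1] + bx * cos(th) - by * sin(th)
  y <- center[2] + bx * sin(th) + by * cos(th)
  sqrt(min((x - px)^2 + (y - py)^2))
}

# cached unmasked-model recovery run (shared by two acceptance checks that
# assess the same measurement against truth and against the nominal mean)
unmasked_recovery_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- benchmark_fiber_length(length_model_unmasked(),
                                       n_total = 500, per_scene = 25,
                                       image_px = 1400, seed = 77)
    cache
  }
})

# deterministic small fiber scene reused by several tests
small_fiber_scene <- function(seed = 42, kappa = 2, n = 40) {
  generate_fiber_image(fiber_field_spec(
    image_shape = c(512, 512), n_fibers = n,
    length_model = length_model_masked(60),
    orientation_kappa = kappa, overlap = FALSE, seed = seed))
}
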