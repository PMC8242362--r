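# synthetic fiber-field scenes with exact ground truth
#
# Fibers are straight capsule segments (~2 um wide electrospun fiber
# segments) with axial von Mises orientations and a configurable length
# model, rendered with analytic anti-aliasing, then PSF-blurred and noised.
# The truth table records every fiber's centerline, so the noise-free
# support is exactly reconstructible.

#' Photomasked fiber-length model
#'
#' Normal lengths truncated symmetrically at +/- 3 sd (and at zero), as
#' produced by photomasked crosslinking of fiber mats into segments of a
#' prescribed mean length (means of 60-120 um depending on the mask).
#'
#' @param mean mean segment length, um.
#' @param sd standard deviation, um.
#' @return a `length_model` object.
#' @export
length_model_masked <- function(mean = 90, sd = mean / 6) {
  stop_if_not_scalar_pos(mean, "mean"); stop_if_not_scalar_pos(sd, "sd")
  structure(list(kind = "masked", mean = mean, sd = sd,
                 support = c(max(1e-6, mean - 3 * sd), mean + 3 * sd)),
            class = "length_model")
}

#' Unmasked (vortexed-mat) fiber-length model
#'
#' Truncated lognormal on a fixed support, the heavy-tailed length
#' distribution of fibers broken up by vortexing without a photomask
#' (support 100-550 um, mean 225 um by default). `meanlog` is calibrated
#' numerically so the truncated mean equals `mean`.
#'
#' @param mean target mean of the truncated distribution, um.
#' @param support `c(min, max)` truncation bounds, um.
#' @param sdlog lognormal log-scale sd (shape of the tail).
#' @return a `length_model` object.
#' @export
length_model_unmasked <- function(mean = 225, support = c(100, 550),
                                  sdlog = 0.5) {
  stopifnot(length(support) == 2L, support[1] > 0, support[2] > support[1],
            mean > support[1], mean < support[2])
  tmean <- function(mu) .trunc_lnorm_mean(mu, sdlog, support[1], support[2])
  mu <- uniroot(function(m) tmean(m) - mean,
                lower = log(support[1]) - 3, upper = log(support[2]) + 3,
                tol = 1e-10)$root
  structure(list(kind = "unmasked", mean = mean, support = support,
                 meanlog = mu, sdlog = sdlog),
            class = "length_model")
}

# mean of a lognormal truncated to [a, b]
.trunc_lnorm_mean <- function(mu, sdlog, a, b) {
  za <- (log(a) - mu) / sdlog; zb <- (log(b) - mu) / sdlog
  num <- pnorm(zb - sdlog) - pnorm(za - sdlog)
  den <- pnorm(zb) - pnorm(za)
  exp(mu + sdlog^2 / 2) * num / den
}

#' Sample fiber lengths from a length model
#' @param model a `length_model`.
#' @param n number of draws.
#' @return lengths in um, all within the model support.
#' @export
sample_lengths <- function(model, n) {
  stopifnot(inherits(model, "length_model"))
  if (model$kind == "masked") {
    lo <- model$support[1]; hi <- model$support[2]
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, model$mean, model$sd)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
  } else {
    pa <- plnorm(model$support[1], model$meanlog, model$sdlog)
    pb <- plnorm(model$support[2], model$meanlog, model$sdlog)
    qlnorm(pa + runif(n) * (pb - pa), model$meanlog, model$sdlog)
  }
}

#' Specification of a synthetic fiber-field scene
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param n_fibers number of fibers.
#' @param diameter_mean fiber diameter, um (electrospun fibers are ~2 um).
#' @param length_model a [length_model_masked()] or [length_model_unmasked()].
#' @param orientation_kappa axial von Mises concentration (0 = isotropic).
#' @param mean_axis preferred axis, degrees.
#' @param noise Gaussian background sd (image units).
#' @param blur_sigma PSF Gaussian sigma, pixels.
#' @param overlap if `FALSE`, fibers are placed with rejection sampling so
#'   rendered capsules never touch (each connected component is one fiber).
#' @param seed RNG seed; identical spec + seed gives bit-identical scenes.
#' @return a `fiber_field_spec` object.
#' @export
fiber_field_spec <- function(image_shape = c(1024, 1024), pixel_size = 0.5,
                             n_fibers = 150, diameter_mean = 2,
                             length_model = length_model_masked(90),
                             orientation_kappa = 2, mean_axis = 0,
                             noise = 0.02, blur_sigma = 1,
                             overlap = TRUE, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16))
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(diameter_mean, "diameter_mean")
  stopifnot(inherits(length_model, "length_model"))
  if (orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  max_len_px <- max(length_model$support) / pixel_size
  if (max_len_px + diameter_mean / pixel_size + 4 > min(image_shape))
    stop(sprintf(paste0("image too small: the longest possible fiber ",
                        "(%.0f px) does not fit in a %d x %d image"),
                 max_len_px, image_shape[1], image_shape[2]))
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, n_fibers = as.integer(n_fibers),
                 diameter_mean = diameter_mean, length_model = length_model,
                 orientation_kappa = orientation_kappa, mean_axis = mean_axis,
                 noise = noise, blur_sigma = blur_sigma, overlap = overlap,
                 seed = as.integer(seed)),
            class = "fiber_field_spec")
}

# rasterize a fiber truth table onto a blank canvas (noise-free coverage)
rasterize_fibers <- function(fibers, image_shape, pixel_size) {
  img <- blank_image(image_shape)
  for (i in seq_len(nrow(fibers))) {
    img <- draw_capsule(img, fibers$x0[i], fibers$y0[i],
                        fibers$x1[i], fibers$y1[i],
                        fibers$diameter_um[i] / pixel_size)
  }
  img
}

#' Generate a synthetic fiber-field image
#'
#' Renders anti-aliased fiber capsules with the requested diameter, length
#' and axial-orientation statistics, applies Gaussian PSF blur and additive
#' background noise, and returns the image together with the per-fiber
#' ground-truth table.
#'
#' @param spec a [fiber_field_spec()].
#' @return list of class `fiber_scene`: `image` (matrix), `support`
#'   (noise-free logical mask), `fibers` (data.frame: `fiber`, endpoint and
#'   center coordinates in 0-based px, `angle` deg, `length_um`,
#'   `diameter_um`), and the `spec`.
#' @export
generate_fiber_image <- function(spec) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  ps <- spec$pixel_size
  with_seed(spec$seed, {
    n <- spec$n_fibers
    angles <- sample_axial_angles(n, spec$mean_axis, spec$orientation_kappa)
    lengths <- sample_lengths(spec$length_model, n)
    w_px <- spec$diameter_mean / ps
    margin <- w_px / 2 + 2
    h <- spec$image_shape[1]; wd <- spec$image_shape[2]
    x0 <- x1 <- y0 <- y1 <- numeric(n)
    placed <- 0L
    fails <- 0L
    while (placed < n && fails < 20000L) {
      i <- placed + 1L
      L2 <- lengths[i] / ps / 2
      dx <- cos(deg2rad(angles[i])) * L2
      dy <- sin(deg2rad(angles[i])) * L2
      lox <- margin + abs(dx); hix <- wd - 1 - margin - abs(dx)
      loy <- margin + abs(dy); hiy <- h - 1 - margin - abs(dy)
      if (hix <= lox || hiy <= loy) stop("fiber does not fit in the image")
      cx <- runif(1, lox, hix); cy <- runif(1, loy, hiy)
      if (!spec$overlap && placed > 0L) {
        clear <- w_px + 2
        ok <- TRUE
        for (j in seq_len(placed)) {
          if (segment_segment_distance(
                c(cx - dx, cy - dy), c(cx + dx, cy + dy),
                c(x0[j], y0[j]), c(x1[j], y1[j])) < clear) { ok <- FALSE; break }
        }
        if (!ok) { fails <- fails + 1L; next }
      }
      x0[i] <- cx - dx; y0[i] <- cy - dy
      x1[i] <- cx + dx; y1[i] <- cy + dy
      placed <- i
      fails <- 0L
    }
    if (placed < n)
      stop(sprintf(paste0("could only place %d of %d non-overlapping fibers;",
                          " reduce n_fibers or enlarge the image"), placed, n))
    fibers <- data.frame(fiber = seq_len(n), x0 = x0, y0 = y0, x1 = x1,
                         y1 = y1, cx = (x0 + x1) / 2, cy = (y0 + y1) / 2,
                         angle = angles, length_um = lengths,
                         diameter_um = spec$diameter_mean)
    clean <- rasterize_fibers(fibers, spec$image_shape, ps)
    img <- apply_psf_noise(clean, spec$blur_sigma, spec$noise)
    structure(list(image = img, support = clean > 0, fibers = fibers,
                   spec = spec), class = "fiber_scene")
  })
}

#' @export
print.fiber_scene <- function(x, ...) {
  cat(sprintf("fiber_scene: %d fibers, %dx%d px at %.2g um/px (%s lengths, kappa=%g)\n",
              nrow(x$fibers), x$spec$image_shape[1], x$spec$image_shape[2],
              x$spec$pixel_size, x$spec$length_model$kind,
              x$spec$orientation_kappa))
  invisible(x)
}
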