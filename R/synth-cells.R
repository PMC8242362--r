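# synthetic tenocyte (elongated-cell) and Hoechst/PI viability scenes

#' Generate a synthetic tenocyte (F-actin) image
#'
#' Elongated ellipse cells with axial von Mises orientations, placed without
#' overlap by rejection sampling (each ellipse is enclosed in a capsule for
#' the clearance test). With `aspect_ratio = 1` cells are round and their
#' orientation is undefined; the truth table flags them isotropic.
#'
#' @param n_cells number of cells (>= 1).
#' @param orientation_kappa axial concentration of cell orientations.
#' @param aspect_ratio major/minor axis ratio, >= 1.
#' @param mean_axis preferred axis, degrees.
#' @param cell_area mean cell area, um^2.
#' @param image_shape `c(rows, cols)`, px.
#' @param pixel_size um/px.
#' @param noise,blur_sigma background noise sd and PSF sigma (px).
#' @param seed RNG seed.
#' @return list of class `tenocyte_scene`: `image`, `support`, `cells`
#'   (data.frame: `cell`, `cx`, `cy` 0-based px, `angle` deg or NA,
#'   `aspect_ratio`, `area_um2`, `isotropic`), `spec` fields.
#' @export
generate_tenocyte_image <- function(n_cells, orientation_kappa = 4,
                                    aspect_ratio = 4, mean_axis = 0,
                                    cell_area = 500,
                                    image_shape = c(768, 768),
                                    pixel_size = 0.5, noise = 0.02,
                                    blur_sigma = 1, seed = 1L) {
  stopifnot(n_cells >= 1, aspect_ratio >= 1, orientation_kappa >= 0)
  stop_if_not_scalar_pos(cell_area, "cell_area")
  with_seed(seed, {
    area_px <- cell_area / pixel_size^2
    a <- sqrt(area_px * aspect_ratio / pi)   # semi-major, px
    b <- a / aspect_ratio                    # semi-minor, px
    iso <- aspect_ratio <= 1
    angles <- if (iso) rep(NA_real_, n_cells)
              else sample_axial_angles(n_cells, mean_axis, orientation_kappa)
    h <- image_shape[1]; w <- image_shape[2]
    margin <- a + 2
    if (2 * margin >= min(h, w)) stop("cells do not fit in the image")
    cx <- cy <- numeric(n_cells)
    seg <- function(i) {         # enclosing capsule of ellipse i
      th <- deg2rad(if (iso) 0 else angles[i])
      d <- (a - b)
      list(p0 = c(cx[i] - d * cos(th), cy[i] - d * sin(th)),
           p1 = c(cx[i] + d * cos(th), cy[i] + d * sin(th)))
    }
    placed <- 0L; fails <- 0L
    while (placed < n_cells && fails < 10000L) {
      i <- placed + 1L
      cx[i] <- runif(1, margin, w - 1 - margin)
      cy[i] <- runif(1, margin, h - 1 - margin)
      si <- seg(i); ok <- TRUE
      if (placed > 0L) for (j in seq_len(placed)) {
        sj <- seg(j)
        if (segment_segment_distance(si$p0, si$p1, sj$p0, sj$p1) < 2 * b + 2) {
          ok <- FALSE; break
        }
      }
      if (ok) { placed <- i; fails <- 0L } else fails <- fails + 1L
    }
    if (placed < n_cells)
      stop(sprintf(paste0("could only place %d of %d non-overlapping cells; ",
                          "the requested density is too high for the image"),
                   placed, n_cells))
    img <- blank_image(image_shape)
    for (i in seq_len(n_cells))
      img <- draw_ellipse_shape(img, cx[i], cy[i], a, b,
                                rotation = if (iso) 0 else angles[i])
    clean <- img
    img <- apply_psf_noise(img, blur_sigma, noise)
    cells <- data.frame(cell = seq_len(n_cells), cx = cx, cy = cy,
                        angle = angles, aspect_ratio = aspect_ratio,
                        area_um2 = cell_area, isotropic = iso)
    structure(list(image = img, support = clean > 0, cells = cells,
                   pixel_size = pixel_size, seed = seed,
                   orientation_kappa = orientation_kappa,
                   mean_axis = mean_axis),
              class = "tenocyte_scene")
  })
}

#' Generate a synthetic Hoechst/PI viability scene
#'
#' All nuclei appear in the Hoechst channel; exactly
#' `round(n_nuclei * dead_fraction)` of them (round-half-even) also carry
#' PI signal. Nuclei are placed with centroid spacing of at least one
#' nucleus diameter so counts are recoverable.
#'
#' @param n_nuclei number of nuclei.
#' @param dead_fraction fraction of PI-positive (dead) nuclei, in `[0, 1]`.
#' @param nucleus_radius nucleus radius, um.
#' @param image_shape,pixel_size,noise,blur_sigma as in
#'   [generate_tenocyte_image()].
#' @param seed RNG seed.
#' @return list of class `viability_scene`: `hoechst`, `pi` (matrices),
#'   `nuclei` (data.frame: `nucleus`, `cx`, `cy`, `dead`), `n_dead`,
#'   `pixel_size`.
#' @export
generate_viability_image <- function(n_nuclei, dead_fraction,
                                     nucleus_radius = 3.5,
                                     image_shape = c(640, 640),
                                     pixel_size = 0.5, noise = 0.02,
                                     blur_sigma = 1, seed = 1L) {
  stopifnot(n_nuclei >= 1, dead_fraction >= 0, dead_fraction <= 1)
  with_seed(seed, {
    r <- nucleus_radius / pixel_size
    h <- image_shape[1]; w <- image_shape[2]
    margin <- r + 2
    pts <- .place_points(n_nuclei, w, h, margin, min_dist = 2 * r + 1)
    n_dead <- round(n_nuclei * dead_fraction)
    dead <- logical(n_nuclei)
    if (n_dead > 0) dead[sample.int(n_nuclei, n_dead)] <- TRUE
    hoechst <- blank_image(image_shape)
    pi_img <- blank_image(image_shape)
    for (i in seq_len(n_nuclei)) {
      hoechst <- draw_disk(hoechst, pts$x[i], pts$y[i], r)
      if (dead[i]) pi_img <- draw_disk(pi_img, pts$x[i], pts$y[i], r)
    }
    hoechst <- apply_psf_noise(hoechst, blur_sigma, noise)
    pi_img <- apply_psf_noise(pi_img, blur_sigma, noise)
    structure(list(hoechst = hoechst, pi = pi_img,
                   nuclei = data.frame(nucleus = seq_len(n_nuclei),
                                       cx = pts$x, cy = pts$y, dead = dead),
                   n_dead = n_dead, pixel_size = pixel_size, seed = seed),
              class = "viability_scene")
  })
}

# rejection-sample n points with pairwise distance >= min_dist
.place_points <- function(n, w, h, margin, min_dist) {
  x <- y <- numeric(n)
  placed <- 0L; fails <- 0L
  while (placed < n && fails < 5000L) {
    px <- runif(1, margin, w - 1 - margin)
    py <- runif(1, margin, h - 1 - margin)
    if (placed == 0L ||
        min((x[seq_len(placed)] - px)^2 + (y[seq_len(placed)] - py)^2) >=
          min_dist^2) {
      placed <- placed + 1L
      x[placed] <- px; y[placed] <- py
      fails <- 0L
    } else fails <- fails + 1L
  }
  if (placed < n)
    stop(sprintf("could only place %d of %d points at spacing %.1f px",
                 placed, n, min_dist))
  list(x = x, y = y)
}
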