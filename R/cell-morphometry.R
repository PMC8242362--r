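# per-cell orientation statistics and Hoechst/PI viability counting

# per-label moments: centroid, orientation (deg), aspect ratio, area (px)
.label_moments <- function(lab) {
  idx <- which(lab > 0)
  l <- lab[idx]
  rr <- (idx - 1) %% nrow(lab)    # y, 0-based
  cc <- (idx - 1) %/% nrow(lab)   # x
  n <- tabulate(l)
  mx <- tapply(cc, l, mean); my <- tapply(rr, l, mean)
  ids <- as.integer(names(mx))
  u20 <- tapply(cc^2, l, mean) - mx^2
  u02 <- tapply(rr^2, l, mean) - my^2
  u11 <- tapply(cc * rr, l, mean) - mx * my
  disc <- sqrt(((u20 - u02) / 2)^2 + u11^2)
  l1 <- (u20 + u02) / 2 + disc
  l2 <- pmax((u20 + u02) / 2 - disc, 1e-9)
  data.frame(label = ids, cx = as.numeric(mx), cy = as.numeric(my),
             area_px = n[ids],
             orientation = wrap_axial(rad2deg(0.5 * atan2(2 * u11, u20 - u02))),
             aspect_ratio = as.numeric(sqrt(l1 / l2)))
}

#' Segment cells and measure their orientations
#'
#' Otsu threshold, size filter, connected-component labeling; orientation
#' and aspect ratio from the second central moments (equivalent-ellipse
#' fit). Cells rounder than `a_min` get `NA` orientation: a near-circular
#' (stellate) cell has no meaningful axis.
#'
#' @param img actin (or phalloidin) intensity image.
#' @param pixel_size um/px.
#' @param min_area_um2 minimum object area.
#' @param a_min aspect-ratio cutoff below which orientation is undefined.
#' @return data.frame of class `cell_orientation_set` with `cell`, `cx`,
#'   `cy` (px, 0-based), `area_um2`, `aspect_ratio`, `orientation` (deg in
#'   `(-90, 90]` or `NA`). Empty (with a message) if nothing segments.
#' @export
segment_cells <- function(img, pixel_size, min_area_um2 = 50, a_min = 1.2) {
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  mask <- .binarize(img)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1))))
  m <- NULL
  if (any(lab > 0)) {
    m <- .label_moments(lab)
    m <- m[m$area_px * pixel_size^2 >= min_area_um2, , drop = FALSE]
  }
  if (is.null(m) || nrow(m) == 0) {
    message("segment_cells: no objects after filtering")
    m <- data.frame(label = integer(0), cx = numeric(0), cy = numeric(0),
                    area_px = numeric(0), orientation = numeric(0),
                    aspect_ratio = numeric(0))
  }
  out <- data.frame(cell = seq_len(nrow(m)), cx = m$cx, cy = m$cy,
                    area_um2 = m$area_px * pixel_size^2,
                    aspect_ratio = m$aspect_ratio,
                    orientation = ifelse(m$aspect_ratio >= a_min,
                                         m$orientation, NA_real_))
  class(out) <- c("cell_orientation_set", "data.frame")
  out
}

#' Axial orientation histogram with FWHM and band fractions
#'
#' Bins orientations (centered on `reference_axis`) into axial bins and
#' computes the full width at half maximum of the distribution by linear
#' interpolation between bin centers around the modal peak, with
#' wrap-around at +/-90 degrees. If no bin falls below half the peak the
#' distribution is flat at the histogram's resolution and FWHM is 180 by
#' convention.
#'
#' @param angles orientations in degrees (axial); `NA`s dropped.
#' @param bin_width bin width in degrees; must divide 180.
#' @param reference_axis alignment axis, degrees.
#' @return list of class `orientation_histogram`: `mids` (bin centers,
#'   relative to the axis), `counts`, `fwhm` (deg in `(0, 180]`),
#'   `band_fractions` (0-30/30-60/60-90), `n`.
#' @export
orientation_histogram <- function(angles, bin_width = 10, reference_axis = 0) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 10)
    stop("orientation_histogram: need at least 10 angles (FWHM is unstable)")
  if (180 %% bin_width != 0) stop("bin_width must divide 180")
  rel <- wrap_axial(angles - reference_axis)
  nb <- as.integer(180 / bin_width)
  edges <- seq(-90, 90, by = bin_width)
  bin <- pmin(pmax(findInterval(rel, edges, rightmost.closed = TRUE), 1), nb)
  counts <- tabulate(bin, nb)
  mids <- edges[-1] - bin_width / 2
  structure(list(mids = mids, counts = counts, bin_width = bin_width,
                 reference_axis = reference_axis,
                 fwhm = .fwhm_circular(counts, bin_width),
                 band_fractions = angular_stratification(angles, reference_axis),
                 n = length(angles)),
            class = "orientation_histogram")
}

# FWHM of cyclic bin counts (period = nb * bin_width = 180 deg)
.fwhm_circular <- function(counts, bin_width) {
  nb <- length(counts)
  p <- which.max(counts)
  half <- counts[p] / 2
  if (all(counts >= half)) return(180)
  walk <- function(step) {
    j <- p
    for (i in seq_len(nb)) {
      nxt <- ((j - 1 + step) %% nb) + 1
      if (counts[nxt] < half) {
        t <- (counts[j] - half) / (counts[j] - counts[nxt])
        return((i - 1 + t) * bin_width)
      }
      j <- nxt
    }
    (nb / 2) * bin_width
  }
  w <- walk(1L) + walk(-1L)
  min(w, 180)
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("orientation histogram: n = %d, FWHM = %.1f deg, within 30 deg: %.0f%%\n",
              x$n, x$fwhm, 100 * x$band_fractions[["0-30"]]))
  invisible(x)
}

#' Plot an axial orientation histogram
#' @param x an `orientation_histogram`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.orientation_histogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = x$mids,
                    xlab = "orientation relative to axis (deg)",
                    ylab = "cells", ...)
  invisible(x)
}

#' Angular stratification of orientations
#'
#' Fractions of axial angular distance to the reference axis falling in
#' the 0-30, 30-60 and 60-90 degree bands.
#'
#' @param angles orientations in degrees; `NA`s dropped.
#' @param reference_axis alignment axis, degrees.
#' @return named numeric vector (`"0-30"`, `"30-60"`, `"60-90"`) summing
#'   to 1.
#' @export
angular_stratification <- function(angles, reference_axis = 0) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 1) stop("angular_stratification: need at least 1 angle")
  d <- axial_distance(angles, reference_axis)
  c("0-30" = mean(d < 30), "30-60" = mean(d >= 30 & d < 60),
    "60-90" = mean(d >= 60))
}

# nuclei segmentation shared by viability and the migration pipeline:
# threshold -> distance transform -> watershed split of touching nuclei
.segment_nuclei_mask <- function(mask, nucleus_radius_px = 7,
                                 min_area_um2 = 20, pixel_size = 0.5) {
  if (!any(mask)) return(mask * 0L)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  # split tolerance: the pixelated distance-map saddle between two nuclei
  # overlapping ~30% by area is only ~1 px deep, while pixelation wiggle on
  # a single disk stays under ~0.5 px; 0.6 px (scaled up for large nuclei)
  # separates the two regimes
  ws <- EBImage::watershed(dm, tolerance = max(0.6, 0.08 * nucleus_radius_px),
                           ext = 1)
  lab <- as.matrix(EBImage::imageData(ws))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas * pixel_size^2 >= min_area_um2)
  relab <- integer(length(areas)); relab[keep] <- seq_along(keep)
  matrix(ifelse(lab > 0, relab[pmax(lab, 1)], 0L), nrow(lab), ncol(lab))
}

#' Viability from Hoechst and PI channels
#'
#' Segments nuclei on the Hoechst channel (Otsu threshold, distance
#' transform, watershed splitting of touching nuclei) and calls a nucleus
#' PI-positive when its mean PI intensity exceeds the PI background mean by
#' more than 3 background standard deviations.
#'
#' @param hoechst,pi_img co-registered channel images (same shape).
#' @param pixel_size um/px.
#' @param nucleus_radius expected nucleus radius, um (sets the watershed
#'   split tolerance).
#' @param min_area_um2 minimum nucleus area.
#' @return list of class `viability_result`: `n_total`, `n_pi_positive`,
#'   `percent_dead`, `nuclei` (per-nucleus data.frame).
#' @export
viability <- function(hoechst, pi_img, pixel_size = 0.5, nucleus_radius = 3.5,
                      min_area_um2 = 20) {
  stopifnot(identical(dim(hoechst), dim(pi_img)))
  mask <- .binarize(hoechst)
  lab <- .segment_nuclei_mask(mask, nucleus_radius / pixel_size,
                              min_area_um2, pixel_size)
  n <- max(lab)
  if (n == 0) stop("viability: no nuclei detected")
  bg <- pi_img[!mask]
  thr <- mean(bg) + 3 * sd(bg)
  mom <- .label_moments(lab)
  mean_pi <- as.numeric(tapply(pi_img[lab > 0], lab[lab > 0], mean))
  pos <- mean_pi > thr
  structure(list(n_total = n, n_pi_positive = sum(pos),
                 percent_dead = 100 * sum(pos) / n,
                 nuclei = data.frame(nucleus = seq_len(n), cx = mom$cx,
                                     cy = mom$cy, mean_pi = mean_pi,
                                     pi_positive = pos)),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("viability: %d/%d nuclei PI+ (%.1f%% dead)\n",
              x$n_pi_positive, x$n_total, x$percent_dead))
  invisible(x)
}
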