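# fiber-architecture metrics: nematic-tensor anisotropy, per-pixel
# orientation color maps, skeleton-based length/width, entanglement

# Gaussian-presmoothed central-difference gradients; returns interior-valid
# gx, gy (borders zeroed)
.gradients <- function(img, presmooth_sigma = 1) {
  if (presmooth_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = presmooth_sigma))
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' Anisotropy score of an image region
#'
#' Averages the nematic tensor of the gradient-normal direction, weighted
#' by gradient energy, over all pixels whose gradient magnitude exceeds
#' `grad_threshold` times the maximum gradient in the region; this equals
#' the coherency of the region's summed structure tensor. The score is the
#' eigenvalue difference `lambda_1 - lambda_2` of the unit-trace mean
#' tensor: 0 for an isotropic texture, 1 for perfectly parallel structures.
#' The mean orientation is the leading eigenvector's angle. Energy
#' weighting keeps faint anti-aliasing and background pixels from diluting
#' the score of strongly aligned fields.
#'
#' @param img numeric image matrix.
#' @param roi optional logical matrix (same shape) restricting the region.
#' @param grad_threshold gradient-magnitude cutoff, as a fraction of the
#'   region's maximum gradient; the one tunable that affects scores.
#' @param presmooth_sigma Gaussian presmoothing sigma (px) before gradients.
#' @return list of class `anisotropy_result`: `score` in `[0, 1]`,
#'   `mean_orientation` in `(-90, 90]` degrees, `n_pixels_used`.
#' @export
anisotropy_score <- function(img, roi = NULL, grad_threshold = 0.02,
                             presmooth_sigma = 1) {
  g <- .gradients(img, presmooth_sigma)
  mag2 <- g$gx^2 + g$gy^2
  sel <- mag2 > 0
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(img)))
    sel <- sel & roi
  }
  thr2 <- (grad_threshold^2) * max(mag2[if (is.null(roi)) TRUE else roi])
  sel <- sel & (mag2 > thr2)
  n <- sum(sel)
  if (n < 100)
    stop(sprintf(paste0("undefined anisotropy: only %d gradient pixels above",
                        " threshold (>= 100 required)"), n))
  gx <- g$gx[sel]; gy <- g$gy[sel]; m2 <- mag2[sel]
  # doubled angle of the gradient, rotated 180 deg (normal direction),
  # energy-weighted: the coherency of the summed structure tensor
  C <- -sum(gx^2 - gy^2) / sum(m2)
  S <- -sum(2 * gx * gy) / sum(m2)
  structure(list(score = sqrt(C^2 + S^2),
                 mean_orientation = wrap_axial(rad2deg(atan2(S, C) / 2)),
                 n_pixels_used = n),
            class = "anisotropy_result")
}

#' @export
print.anisotropy_result <- function(x, ...) {
  cat(sprintf("anisotropy %.3f, mean orientation %.1f deg (n = %d px)\n",
              x$score, x$mean_orientation, x$n_pixels_used))
  invisible(x)
}

#' Per-pixel orientation map (structure tensor)
#'
#' Smooths the gradient outer product with a Gaussian window and returns,
#' per pixel, the structure orientation (minor eigenvector of the tensor,
#' i.e. along edges/fibers), the coherency `(l1 - l2)/(l1 + l2)` and the
#' tensor energy (trace).
#'
#' @param img numeric image matrix.
#' @param window_sigma Gaussian window sigma, px (> 0).
#' @param presmooth_sigma presmoothing before gradients, px.
#' @return list of class `orientation_map` with matrices `orientation`
#'   (degrees in `(-90, 90]`), `coherency` in `[0, 1]`, `energy`.
#' @export
orientation_map <- function(img, window_sigma = 4, presmooth_sigma = 1) {
  stop_if_not_scalar_pos(window_sigma, "window_sigma")
  g <- .gradients(img, presmooth_sigma)
  sm <- function(m) as.matrix(EBImage::gblur(m, sigma = window_sigma))
  jxx <- sm(g$gx^2); jyy <- sm(g$gy^2); jxy <- sm(g$gx * g$gy)
  tr <- jxx + jyy
  # gradient-major eigenvector angle + 90 deg = structure orientation
  ori <- wrap_axial(rad2deg(0.5 * atan2(2 * jxy, jxx - jyy)) + 90)
  disc <- sqrt(((jxx - jyy) / 2)^2 + jxy^2)
  coh <- ifelse(tr > 1e-12, 2 * disc / tr, 0)
  structure(list(orientation = ori, coherency = pmin(coh, 1), energy = tr),
            class = "orientation_map")
}

#' Render an orientation map as an HSV color image
#'
#' Hue encodes orientation, saturation coherency, value the (normalized)
#' image intensity, matching the familiar orientation-color-map look.
#'
#' @param map an [orientation_map()].
#' @param img the underlying intensity image (for the value channel);
#'   defaults to full brightness.
#' @return an `rows x cols x 3` RGB array in `[0, 1]`.
#' @export
orientation_rgb <- function(map, img = NULL) {
  stopifnot(inherits(map, "orientation_map"))
  h <- (map$orientation + 90) / 180
  s <- map$coherency
  v <- if (is.null(img)) matrix(1, nrow(h), ncol(h))
       else pmin(img / max(img, 1e-12), 1)
  col <- grDevices::hsv(pmin(pmax(h, 0), 1), pmin(pmax(s, 0), 1),
                        pmin(pmax(v, 0), 1))
  rgb <- grDevices::col2rgb(col) / 255
  out <- array(0, c(nrow(h), ncol(h), 3))
  out[, , 1] <- rgb[1, ]; out[, , 2] <- rgb[2, ]; out[, , 3] <- rgb[3, ]
  out
}

# Otsu-threshold an intensity image scaled to [0, 1]; passes masks through
.binarize <- function(img) {
  if (all(img %in% c(0, 1))) return(img > 0)
  mx <- max(img)
  if (mx <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  sc <- img / mx
  sc > EBImage::otsu(EBImage::Image(sc))
}

#' Measure fiber lengths and diameters
#'
#' Thresholds (Otsu, unless a binary mask is given), labels connected
#' components, skeletonizes each by morphological thinning with short-spur
#' pruning, and measures length as the longest geodesic path through the
#' skeleton and diameter as twice the mean medial-axis (distance-map) value
#' over skeleton pixels.
#'
#' @param img intensity image or binary mask.
#' @param pixel_size um/px.
#' @param min_area_um2 components smaller than this are dropped.
#' @param prune_px endpoint-pruning iterations (removes spurs shorter than
#'   this many pixels); the two pruned path ends are compensated in the
#'   reported length.
#' @param threshold `"halfmax"` (half the robust foreground intensity, the
#'   standard choice for width-faithful masks) or `"otsu"`; ignored for
#'   binary input.
#' @return data.frame of class `fiber_measurements`: `fiber`, `length_um`,
#'   `diameter_um`, `area_um2`, `solidity`; the label image is attached as
#'   attribute `labels`. Zero rows (with a message) if nothing is
#'   segmentable.
#' @export
measure_fibers <- function(img, pixel_size, min_area_um2 = 6,
                           prune_px = 3,
                           threshold = c("halfmax", "otsu")) {
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  threshold <- match.arg(threshold)
  mask <- if (all(img %in% c(0, 1)) || threshold == "otsu") .binarize(img)
          else img > 0.5 * quantile(img, 0.999)
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(labels))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas * pixel_size^2 >= min_area_um2)
  empty <- data.frame(fiber = integer(0), length_um = numeric(0),
                      diameter_um = numeric(0), area_um2 = numeric(0),
                      solidity = numeric(0))
  if (length(keep) == 0) {
    message("measure_fibers: no foreground objects after filtering")
    out <- empty
    attr(out, "labels") <- lab * 0L
    class(out) <- c("fiber_measurements", "data.frame")
    return(out)
  }
  relab <- integer(length(areas)); relab[keep] <- seq_along(keep)
  lab <- matrix(ifelse(lab > 0, relab[pmax(lab, 1)], 0L), nrow(lab), ncol(lab))
  mask <- lab > 0
  skel <- cpp_prune(cpp_thin(mask * 1L), prune_px)
  skel_lab <- lab * (skel > 0)
  lens_px <- cpp_skel_lengths(skel_lab)
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  n <- length(keep)
  diam <- vapply(seq_len(n), function(i) {
    s <- skel_lab == i
    if (!any(s)) return(2 * max(dm[lab == i]))
    2 * mean(dm[s])
  }, numeric(1))
  sol <- vapply(seq_len(n), function(i) {
    idx <- which(lab == i)
    rr <- (idx - 1) %% nrow(lab); cc <- (idx - 1) %/% nrow(lab)
    if (length(idx) < 4) return(1)
    h <- grDevices::chull(cc, rr)
    hx <- cc[h]; hy <- rr[h]
    ha <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    if (ha <= 0) 1 else min(1, length(idx) / ha)
  }, numeric(1))
  out <- data.frame(fiber = seq_len(n),
                    length_um = (pmax(lens_px, 1) + 2 * prune_px) * pixel_size,
                    diameter_um = diam * pixel_size,
                    area_um2 = areas[keep] * pixel_size^2,
                    solidity = sol)
  attr(out, "labels") <- lab
  class(out) <- c("fiber_measurements", "data.frame")
  out
}

#' Entangled-area fraction of a fiber field
#'
#' A component is called entangled when its area exceeds
#' `k * single_fiber_area` (several fibers merged) or its solidity falls
#' below `solidity_min` (a loose tangle). The fraction is entangled area
#' over total fiber area.
#'
#' @param measurements a [measure_fibers()] result.
#' @param single_fiber_area expected area of one fiber, um^2 (e.g. mean
#'   length x diameter).
#' @param k area multiple above which a component counts as entangled.
#' @param solidity_min solidity below which a component counts as entangled.
#' @return fraction in `[0, 1]`.
#' @export
entanglement_fraction <- function(measurements, single_fiber_area, k = 3,
                                  solidity_min = 0.2) {
  stopifnot(inherits(measurements, "fiber_measurements"))
  stop_if_not_scalar_pos(single_fiber_area, "single_fiber_area")
  tot <- sum(measurements$area_um2)
  if (tot <= 0) stop("entanglement_fraction: zero total fiber area")
  ent <- measurements$area_um2 > k * single_fiber_area |
         measurements$solidity < solidity_min
  sum(measurements$area_um2[ent]) / tot
}
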