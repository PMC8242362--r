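# rasterization primitives for the synthetic-scene generator
#
# Shapes are drawn with analytic edge anti-aliasing: per-pixel coverage is
# clamp(edge_distance + 0.5, 0, 1) of the pixel center's distance to the
# shape boundary, accumulated with max-blending so the noise-free support
# (coverage > 0) is exactly reproducible from the ground-truth geometry.
# Images are [row, col] matrices; coordinates are 0-based pixel centers.

blank_image <- function(shape) matrix(0, nrow = shape[1], ncol = shape[2])

# pixel-center coordinate grids for a bounding box (1-based matrix indices)
.bbox <- function(shape, x0, x1, y0, y1, pad) {
  rows <- max(1L, floor(min(y0, y1) - pad) + 1L):min(shape[1], ceiling(max(y0, y1) + pad) + 1L)
  cols <- max(1L, floor(min(x0, x1) - pad) + 1L):min(shape[2], ceiling(max(x0, x1) + pad) + 1L)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  list(rows = rows, cols = cols,
       px = matrix(rep(cols - 1, each = length(rows)), nrow = length(rows)),
       py = matrix(rep(rows - 1, times = length(cols)), nrow = length(rows)))
}

.blend_max <- function(img, bb, cov) {
  img[bb$rows, bb$cols] <- pmax(img[bb$rows, bb$cols], cov)
  img
}

# capsule: segment (x0,y0)-(x1,y1) with total width w (pixels); compiled
# rasterizer (the hot path: fiber scenes draw hundreds of long capsules).
# NOTE: blends into `img` in place; callers always own the buffer and
# rebind the return value.
draw_capsule <- function(img, x0, y0, x1, y1, w, value = 1) {
  cpp_draw_capsule(img, x0, y0, x1, y1, w, value)
}

draw_disk <- function(img, cx, cy, r, value = 1) {
  bb <- .bbox(dim(img), cx - r, cx + r, cy - r, cy + r, 1.5)
  if (is.null(bb)) return(img)
  d <- sqrt((bb$px - cx)^2 + (bb$py - cy)^2)
  cov <- pmin(1, pmax(0, r + 0.5 - d))
  .blend_max(img, bb, value * cov)
}

# filled rotated ellipse, semi-axes (a, b) px, rotation degrees
draw_ellipse_shape <- function(img, cx, cy, a, b, rotation = 0, value = 1) {
  ext <- max(a, b)
  bb <- .bbox(dim(img), cx - ext, cx + ext, cy - ext, cy + ext, 1.5)
  if (is.null(bb)) return(img)
  p <- .ellipse_local(as.vector(bb$px), as.vector(bb$py), c(cx, cy), rotation)
  q <- sqrt((p$x / a)^2 + (p$y / b)^2)
  # approximate signed edge distance: (1 - q) scaled by the local radius
  r_loc <- 1 / sqrt((cos(atan2(p$y * a, p$x * b)) / a)^2 +
                    (sin(atan2(p$y * a, p$x * b)) / b)^2)
  cov <- pmin(1, pmax(0, (1 - q) * r_loc + 0.5))
  dim(cov) <- dim(bb$px)
  .blend_max(img, bb, value * cov)
}

# Gaussian blur + additive Gaussian background noise (uses current RNG)
apply_psf_noise <- function(img, blur_sigma = 0, noise = 0) {
  if (blur_sigma > 0) img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
  if (noise > 0) img <- img + matrix(rnorm(length(img), 0, noise), nrow = nrow(img))
  pmax(img, 0)
}
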