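# TIFF stack I/O, commented-CSV helpers, config handling

#' Write a multi-channel image stack as TIFF
#'
#' Channels are written as consecutive 32-bit float pages (order: nuclei,
#' actin, fiber where applicable), intensities clipped to `[0, 1]`.
#'
#' @param channels a matrix or list of matrices (same shape).
#' @param path output path.
#' @param pixel_size um/px; accepted for interface symmetry with
#'   [read_stack()] (this TIFF writer does not store resolution tags, so
#'   the pixel size travels in the run config / truth CSVs).
#' @return `path`, invisibly.
#' @export
write_stack <- function(channels, path, pixel_size = NULL) {
  if (is.matrix(channels)) channels <- list(channels)
  stopifnot(length(unique(vapply(channels, function(m)
    paste(dim(m), collapse = "x"), ""))) == 1)
  channels <- lapply(channels, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(channels, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a TIFF image stack
#'
#' Multi-page TIFFs come back as a list of channel matrices. Pixel size is
#' taken from the resolution metadata when present; a `pixel_size` argument
#' wins over metadata (with a warning if the two disagree).
#'
#' @param path TIFF file (1-3 channels/pages).
#' @param pixel_size optional um/px override.
#' @return list: `channels` (list of matrices), `pixel_size` (um/px or
#'   `NA`), `n_channels`.
#' @export
read_stack <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("read_stack: no such file '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  meta_ps <- NA_real_
  info <- attributes(tiff::readTIFF(path, info = TRUE, payload = FALSE))
  if (!is.null(info$x.resolution) && info$x.resolution > 0) {
    per_unit <- info$x.resolution
    unit <- info$resolution.unit %||% "inch"
    um <- switch(unit, cm = 1e4, inch = 25400, 1e4)
    meta_ps <- um / per_unit
  }
  ps <- meta_ps
  if (!is.null(pixel_size)) {
    if (is.finite(meta_ps) && abs(meta_ps - pixel_size) > 1e-6 * pixel_size)
      warning(sprintf(paste0("pixel size %.4g um/px from metadata overridden",
                             " by configured %.4g um/px"), meta_ps, pixel_size))
    ps <- pixel_size
  }
  list(channels = pages, pixel_size = ps, n_channels = length(pages))
}

# write a data.frame as CSV with '#'-prefixed header comment lines
write_csv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header))
    writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# short stable hash of an R object (FNV-1a over its serialization)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- h - h %% 256 + bitwXor(h %% 256, b)   # xor on the low byte
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a spheroid/fiber scene to disk
#'
#' The image channels go to an OME-style multi-page TIFF and the ground
#' truth to CSV files with `#` comment headers carrying the seed and
#' config hash.
#'
#' @param scene a `spheroid_scene`, `fiber_scene`, `tenocyte_scene` or
#'   `viability_scene`.
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, basename = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, basename)
  seed <- scene$spec$seed %||% scene$seed %||% NA
  hdr <- c(seed = seed, config_hash = config_hash(scene$spec %||% scene$seed),
           package = as.character(packageVersion("fibermag")))
  paths <- character(0)
  if (inherits(scene, "spheroid_scene")) {
    ps <- scene$spec$pixel_size
    p <- paste0(stem, ".tif")
    write_stack(list(scene$nuclei, scene$actin), p, ps)
    paths <- c(paths, p,
               write_csv_commented(scene$truth$outgrowths,
                                   paste0(stem, "_outgrowths.csv"), hdr),
               write_csv_commented(scene$truth$nuclei,
                                   paste0(stem, "_nuclei.csv"), hdr),
               write_csv_commented(scene$truth$totals,
                                   paste0(stem, "_totals.csv"), hdr))
  } else if (inherits(scene, "fiber_scene")) {
    p <- paste0(stem, ".tif")
    write_stack(scene$image / max(scene$image), p, scene$spec$pixel_size)
    paths <- c(paths, p,
               write_csv_commented(scene$fibers, paste0(stem, "_fibers.csv"), hdr))
  } else if (inherits(scene, "tenocyte_scene")) {
    p <- paste0(stem, ".tif")
    write_stack(scene$image / max(scene$image), p, scene$pixel_size)
    paths <- c(paths, p,
               write_csv_commented(scene$cells, paste0(stem, "_cells.csv"), hdr))
  } else if (inherits(scene, "viability_scene")) {
    p <- paste0(stem, ".tif")
    write_stack(list(scene$hoechst / max(scene$hoechst),
                     scene$pi / max(scene$pi, 1e-9)), p, scene$pixel_size)
    paths <- c(paths, p,
               write_csv_commented(scene$nuclei, paste0(stem, "_nuclei.csv"), hdr))
  } else stop("write_scene: unknown scene class")
  invisible(paths)
}
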