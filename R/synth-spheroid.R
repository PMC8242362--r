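# synthetic spheroid-outgrowth scenes with exact ground truth
#
# A scene is a dense elliptical spheroid body (filled actin + crowded
# nuclei) plus outgrowths of three classes: contiguous multicellular
# strands, disconnected multicellular clusters, and disconnected single
# cells, at known directions, path lengths and gaps. The truth tables are
# the oracle for the migration pipeline.

.OUTGROWTH_CLASSES <- c("contiguous_strand", "disconnected_cluster",
                        "disconnected_single")

#' Specification of a synthetic spheroid scene
#'
#' @param body list with `center` (`c(x, y)` px, 0-based), `semiaxes`
#'   (`c(a, b)` px), `rotation` (deg, default 0) and `n_nuclei`.
#' @param outgrowths data.frame with columns `class` (one of
#'   `"contiguous_strand"`, `"disconnected_cluster"`,
#'   `"disconnected_single"`), `direction` (deg, full circle),
#'   `path_length` (um, strand length or cluster/cell extent),
#'   `n_nuclei` (>= 1), `gap_to_body` (um; 0 iff contiguous). May have
#'   zero rows.
#' @param direction_kappa concentration used when directions were sampled
#'   (recorded for reference; see [random_spheroid_spec()]).
#' @param nucleus_radius um.
#' @param strand_width strand (and protrusion) width, um.
#' @param image_shape `c(rows, cols)` px.
#' @param pixel_size um/px.
#' @param psf_sigma,noise PSF sigma (px) and background noise sd.
#' @param seed RNG seed.
#' @return a `spheroid_scene_spec` object.
#' @export
spheroid_scene_spec <- function(body, outgrowths = NULL, direction_kappa = 0,
                                nucleus_radius = 4, strand_width = 14,
                                image_shape = c(1024, 1024), pixel_size = 0.5,
                                psf_sigma = 1, noise = 0.02, seed = 1L) {
  stopifnot(is.list(body), length(body$center) == 2L,
            length(body$semiaxes) == 2L, all(body$semiaxes > 0))
  body$rotation <- body$rotation %||% 0
  body$n_nuclei <- body$n_nuclei %||% 50L
  if (is.null(outgrowths))
    outgrowths <- data.frame(class = character(), direction = numeric(),
                             path_length = numeric(), n_nuclei = integer(),
                             gap_to_body = numeric())
  stopifnot(all(outgrowths$class %in% .OUTGROWTH_CLASSES),
            all(outgrowths$n_nuclei >= 1))
  single <- outgrowths$class == "disconnected_single"
  strand <- outgrowths$class == "contiguous_strand"
  if (any(single & outgrowths$n_nuclei != 1))
    stop("disconnected_single outgrowths must have exactly 1 nucleus")
  if (any(outgrowths$class == "disconnected_cluster" & outgrowths$n_nuclei < 2))
    stop("disconnected_cluster outgrowths must have >= 2 nuclei")
  if (any(xor(strand, outgrowths$gap_to_body == 0)))
    stop("gap_to_body must be 0 for contiguous strands and > 0 otherwise")
  structure(list(body = body, outgrowths = outgrowths,
                 direction_kappa = direction_kappa,
                 nucleus_radius = nucleus_radius, strand_width = strand_width,
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 noise = noise, seed = as.integer(seed)),
            class = "spheroid_scene_spec")
}

#' Randomized spheroid scene specification
#'
#' Draws a scene specification with outgrowth directions from an axial von
#' Mises distribution about `mean_axis` (each direction then assigned to one
#' of the two axial senses at random), strand lengths, gaps and nucleus
#' counts from calibrated ranges.
#'
#' @param seed RNG seed (also becomes the scene seed).
#' @param direction_kappa axial concentration of outgrowth directions
#'   (0 = uniform).
#' @param n_strands,n_clusters,n_singles outgrowth counts per class.
#' @param mean_axis alignment axis, degrees.
#' @param min_direction_sep if > 0, directions are re-drawn until pairwise
#'   separated by at least this many degrees (use for recovery benchmarks
#'   where outgrowths must not merge; 0 leaves the distribution untouched).
#' @param image_shape,pixel_size passed through to [spheroid_scene_spec()].
#' @return a `spheroid_scene_spec`.
#' @export
random_spheroid_spec <- function(seed, direction_kappa = 0, n_strands = 3,
                                 n_clusters = 2, n_singles = 3,
                                 mean_axis = 0, min_direction_sep = 0,
                                 image_shape = c(1024, 1024),
                                 pixel_size = 0.5) {
  n_out <- n_strands + n_clusters + n_singles
  with_seed(seed + 202600L, {
    draw_dir <- function()
      wrap_axial(sample_axial_angles(1, mean_axis, direction_kappa)) +
        sample(c(0, 180), 1)
    dirs <- numeric(0)
    for (i in seq_len(n_out)) {
      for (tr in 1:500) {
        d <- draw_dir()
        sep <- if (length(dirs) == 0) Inf else
          min(pmin(abs(d - dirs) %% 360, 360 - abs(d - dirs) %% 360))
        if (sep >= min_direction_sep) break
        if (tr == 500) stop("cannot satisfy min_direction_sep; reduce outgrowth count")
      }
      dirs <- c(dirs, d)
    }
    cls <- c(rep("contiguous_strand", n_strands),
             rep("disconnected_cluster", n_clusters),
             rep("disconnected_single", n_singles))
    path <- ifelse(cls == "contiguous_strand", runif(n_out, 80, 130),
                   runif(n_out, 20, 40))
    nn <- ifelse(cls == "contiguous_strand", pmax(2, round(path / 28)),
          ifelse(cls == "disconnected_cluster", sample(2:5, n_out, TRUE), 1L))
    gap <- ifelse(cls == "contiguous_strand", 0, runif(n_out, 15, 35))
    ctr <- rev(image_shape) / 2 + runif(2, -8, 8)   # (x, y)
    ax <- c(runif(1, 75, 90), runif(1, 60, 72)) / pixel_size
    spheroid_scene_spec(
      body = list(center = ctr, semiaxes = ax, rotation = runif(1, 0, 180),
                  n_nuclei = 50L),
      outgrowths = data.frame(class = cls, direction = dirs,
                              path_length = path, n_nuclei = as.integer(nn),
                              gap_to_body = gap),
      direction_kappa = direction_kappa, image_shape = image_shape,
      pixel_size = pixel_size, seed = seed)
  })
}

# hexagonal-lattice offsets around the origin, closest first
.hex_offsets <- function(n, spacing) {
  k <- ceiling(sqrt(n)) + 2
  g <- expand.grid(i = -k:k, j = -k:k)
  x <- spacing * (g$i + 0.5 * (g$j %% 2))
  y <- spacing * 0.866 * g$j
  o <- order(x^2 + y^2)
  list(x = x[o][seq_len(n)], y = y[o][seq_len(n)])
}

#' Generate a synthetic spheroid scene
#'
#' Renders the two-channel image stack (nuclei, F-actin) and the complete
#' ground truth: per-outgrowth class, nucleus centroids and distances to the
#' body boundary, areas and maximal depths, plus scene totals stratified by
#' contiguity.
#'
#' @param spec a [spheroid_scene_spec()] (or [random_spheroid_spec()]).
#' @return list of class `spheroid_scene` with elements `nuclei`, `actin`
#'   (image matrices), `truth` (list `outgrowths`, `nuclei`, `totals`),
#'   `body` and `spec`.
#' @export
generate_spheroid_scene <- function(spec) {
  stopifnot(inherits(spec, "spheroid_scene_spec"))
  ps <- spec$pixel_size
  shp <- spec$image_shape
  body <- spec$body
  r_nuc <- spec$nucleus_radius / ps
  w_str <- spec$strand_width / ps
  og <- spec$outgrowths
  with_seed(spec$seed, {
    actin <- blank_image(shp)
    nuc_img <- blank_image(shp)
    actin <- draw_ellipse_shape(actin, body$center[1], body$center[2],
                                body$semiaxes[1], body$semiaxes[2],
                                body$rotation)
    # body nuclei: uniform in the 0.9-scaled ellipse, overlap allowed
    nb <- body$n_nuclei
    bx <- by <- numeric(nb); got <- 0L
    while (got < nb) {
      px <- runif(1, body$center[1] - body$semiaxes[1],
                  body$center[1] + body$semiaxes[1])
      py <- runif(1, body$center[2] - body$semiaxes[2],
                  body$center[2] + body$semiaxes[2])
      if (in_ellipse(px, py, body$center, 0.9 * body$semiaxes, body$rotation)) {
        got <- got + 1L; bx[got] <- px; by[got] <- py
      }
    }
    for (i in seq_len(nb)) nuc_img <- draw_disk(nuc_img, bx[i], by[i], r_nuc)
    nuclei_truth <- data.frame(outgrowth = integer(0), cx = numeric(0),
                               cy = numeric(0), dist_um = numeric(0))
    if (nb > 0)
      nuclei_truth <- data.frame(outgrowth = 0L, cx = bx, cy = by, dist_um = 0)
    og_rows <- list()
    dist_to_body <- function(x, y)
      ellipse_distance(x, y, body$center, body$semiaxes, body$rotation) * ps
    for (k in seq_len(nrow(og))) {
      cls <- og$class[k]; dir <- og$direction[k]
      u <- c(cos(deg2rad(dir)), sin(deg2rad(dir)))
      bpt <- ellipse_ray_point(body$center, body$semiaxes, body$rotation, dir)
      gap_px <- og$gap_to_body[k] / ps
      n_k <- og$n_nuclei[k]
      layer <- blank_image(shp)
      ncx <- ncy <- numeric(n_k)
      if (cls == "contiguous_strand") {
        L <- og$path_length[k] / ps
        p0 <- bpt - 4 * u
        p1 <- bpt + L * u
        layer <- draw_capsule(layer, p0[1], p0[2], p1[1], p1[2], w_str)
        d0 <- max(2 * r_nuc, 24)
        if (L - d0 - r_nuc < (n_k - 1) * (2 * r_nuc + 1))
          stop(sprintf("outgrowth %d: path too short for %d nuclei", k, n_k))
        dpos <- if (n_k == 1) (d0 + L - r_nuc) / 2
                else seq(d0, L - r_nuc, length.out = n_k)
        jit_max <- max(0, w_str / 2 - r_nuc - 1)
        for (i in seq_len(n_k)) {
          jit <- runif(1, -jit_max, jit_max)
          p <- bpt + dpos[i] * u + jit * c(-u[2], u[1])
          ncx[i] <- p[1]; ncy[i] <- p[2]
        }
      } else if (cls == "disconnected_cluster") {
        off <- .hex_offsets(n_k, 2 * r_nuc + 1)
        rot <- runif(1, 0, 360)
        cr <- cos(deg2rad(rot)); sr <- sin(deg2rad(rot))
        ox <- off$x * cr - off$y * sr; oy <- off$x * sr + off$y * cr
        r_cell <- 1.6 * r_nuc
        ext <- max(sqrt(ox^2 + oy^2)) + r_cell
        ctr <- bpt + (gap_px + ext + 1) * u
        for (it in 1:3) {   # shift until the nearest actin edge sits at gap
          m <- min(ellipse_distance(ctr[1] + ox, ctr[2] + oy, body$center,
                                    body$semiaxes, body$rotation) - r_cell)
          ctr <- ctr + (gap_px + 1 - m) * u
        }
        ncx <- ctr[1] + ox; ncy <- ctr[2] + oy
        for (i in seq_len(n_k))
          layer <- draw_disk(layer, ncx[i], ncy[i], r_cell)
      } else {  # disconnected_single
        a_c <- max(og$path_length[k] / 2, 8) / ps   # elongated cell half-length
        b_c <- max(a_c / 2.5, r_nuc + 1)
        ctr <- bpt + (gap_px + a_c + 1) * u
        for (it in 1:3) {
          tip <- ctr - a_c * u
          m <- dist_to_body(tip[1], tip[2]) / ps
          ctr <- ctr + (gap_px + 1 - m) * u
        }
        layer <- draw_ellipse_shape(layer, ctr[1], ctr[2], a_c, b_c, dir)
        ncx <- ctr[1]; ncy <- ctr[2]
      }
      sup_idx <- which(layer > 0)
      if (length(sup_idx) == 0 ||
          any(ncx < 1 | ncx > shp[2] - 2 | ncy < 1 | ncy > shp[1] - 2)) {
        stop(sprintf(paste0("outgrowth %d (%s) exits the image bounds; ",
                            "use a larger canvas"), k, cls))
      }
      rr <- (sup_idx - 1) %% shp[1]          # 0-based row (y)
      cc <- (sup_idx - 1) %/% shp[1]         # 0-based col (x)
      on_edge <- rr == 0 | cc == 0 | rr == shp[1] - 1 | cc == shp[2] - 1
      if (any(on_edge))
        stop(sprintf(paste0("outgrowth %d (%s) exits the image bounds; ",
                            "use a larger canvas"), k, cls))
      outside <- !in_ellipse(cc, rr, body$center, body$semiaxes, body$rotation)
      depth <- if (any(outside))
        max(ellipse_distance(cc[outside], rr[outside], body$center,
                             body$semiaxes, body$rotation)) * ps else 0
      nd <- dist_to_body(ncx, ncy)
      for (i in seq_len(n_k)) nuc_img <- draw_disk(nuc_img, ncx[i], ncy[i], r_nuc)
      actin <- pmax(actin, layer)
      nuclei_truth <- rbind(nuclei_truth,
                            data.frame(outgrowth = k, cx = ncx, cy = ncy,
                                       dist_um = nd))
      og_rows[[k]] <- data.frame(
        outgrowth = k, class = cls, direction = dir,
        gap_um = og$gap_to_body[k], n_nuclei = n_k,
        area_um2 = sum(outside) * ps^2, max_depth_um = depth,
        total_distance_um = sum(nd),
        contiguous = cls == "contiguous_strand")
    }
    og_truth <- if (length(og_rows)) do.call(rbind, og_rows) else
      data.frame(outgrowth = integer(0), class = character(0),
                 direction = numeric(0), gap_um = numeric(0),
                 n_nuclei = integer(0), area_um2 = numeric(0),
                 max_depth_um = numeric(0), total_distance_um = numeric(0),
                 contiguous = logical(0))
    totals <- .spheroid_totals(og_truth)
    support <- list(actin = actin > 0, nuclei = nuc_img > 0)
    actin_n <- apply_psf_noise(actin, spec$psf_sigma, spec$noise)
    nuc_n <- apply_psf_noise(nuc_img, spec$psf_sigma, spec$noise)
    structure(list(nuclei = nuc_n, actin = actin_n, support = support,
                   truth = list(outgrowths = og_truth, nuclei = nuclei_truth,
                                totals = totals),
                   body = body, spec = spec),
              class = "spheroid_scene")
  })
}

.spheroid_totals <- function(og) {
  strat <- function(rows) data.frame(
    n_outgrowths = nrow(rows),
    n_migratory_cells = sum(rows$n_nuclei),
    total_migration_distance_um = sum(rows$total_distance_um),
    max_invasion_depth_um = if (nrow(rows)) max(rows$max_depth_um) else 0)
  rbind(cbind(stratum = "contiguous", strat(og[og$contiguous, , drop = FALSE])),
        cbind(stratum = "disconnected", strat(og[!og$contiguous, , drop = FALSE])),
        cbind(stratum = "all", strat(og)))
}

#' @export
print.spheroid_scene <- function(x, ...) {
  t <- x$truth$totals
  cat(sprintf(paste0("spheroid_scene: %d outgrowths, %d migratory nuclei, ",
                     "total distance %.0f um, max depth %.0f um\n"),
              t$n_outgrowths[t$stratum == "all"],
              t$n_migratory_cells[t$stratum == "all"],
              t$total_migration_distance_um[t$stratum == "all"],
              t$max_invasion_depth_um[t$stratum == "all"]))
  invisible(x)
}
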