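# spheroid-outgrowth migration pipeline: projection, masking, body ellipse,
# outgrowth contiguity, nucleus splitting, phenotype calling, migration
# metrics, population aggregation and spreadsheet export

#' Maximum-intensity projection of a Z-stack
#'
#' @param stack a 3D array `[rows, cols, z]`, a 2D matrix (returned as is),
#'   or a list of such (one per channel; all channels must agree in shape).
#' @return a matrix, or a list of matrices for list input.
#' @export
project_stack <- function(stack) {
  if (is.list(stack)) {
    dims <- lapply(stack, function(s) dim(s)[1:2])
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      stop("project_stack: channels differ in shape")
    return(lapply(stack, project_stack))
  }
  d <- dim(stack)
  if (length(d) == 2) return(stack)
  if (length(d) != 3 || d[3] < 1) stop("project_stack: need a [rows, cols, z] array")
  apply(stack, c(1, 2), max)
}

#' Threshold and size-filter a channel
#'
#' Otsu threshold followed by removal of connected components smaller than
#' `min_object_area` (defaults: 20 um^2 suits nuclei, 50 um^2 actin).
#'
#' @param img intensity image.
#' @param pixel_size um/px.
#' @param min_object_area um^2.
#' @return logical mask.
#' @export
preprocess_channel <- function(img, pixel_size, min_object_area = 20) {
  mask <- .binarize(img)
  if (!any(mask)) return(mask)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1))))
  areas <- tabulate(lab[lab > 0])
  keep <- areas * pixel_size^2 >= min_object_area
  mask[lab > 0] <- keep[lab[lab > 0]]
  mask
}

#' Body region of interest (ellipse)
#'
#' @param center `c(x, y)` px (0-based).
#' @param semiaxes `c(a, b)` px.
#' @param rotation degrees.
#' @return a `body_roi` object.
#' @export
body_roi <- function(center, semiaxes, rotation = 0) {
  stopifnot(length(center) == 2L, length(semiaxes) == 2L, all(semiaxes > 0))
  structure(list(center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 rotation = as.numeric(rotation)), class = "body_roi")
}

#' @export
print.body_roi <- function(x, ...) {
  cat(sprintf("body_roi: center (%.1f, %.1f), semi-axes (%.1f, %.1f) px, rot %.1f deg\n",
              x$center[1], x$center[2], x$semiaxes[1], x$semiaxes[2],
              x$rotation))
  invisible(x)
}

# morphological opening via two distance transforms (fast for large discs)
.open_mask <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  core <- dm > radius
  if (!any(core)) return(core)
  dm2 <- as.matrix(EBImage::distmap(EBImage::Image((!core) * 1)))
  dm2 <= radius
}

#' Fit (or accept) the spheroid-body ellipse
#'
#' With a `user_roi` the ellipse is used verbatim. Otherwise the mask is
#' morphologically opened (disc of `opening_um`) to strip strand-scale
#' protrusions, the largest remaining component is fitted with an
#' equivalent ellipse from its second moments, and the semi-axes are
#' inflated by `inflate` so the ROI covers the body the way a user-drawn
#' ellipse would.
#'
#' @param mask actin mask (logical), from [preprocess_channel()].
#' @param pixel_size um/px.
#' @param user_roi optional [body_roi()], returned unchanged.
#' @param min_body_area_um2 smallest believable spheroid body.
#' @param opening_um opening disc radius, um.
#' @param inflate semi-axis inflation factor.
#' @return a [body_roi()].
#' @export
segment_body <- function(mask, pixel_size, user_roi = NULL,
                         min_body_area_um2 = 2000, opening_um = 10,
                         inflate = 1.05) {
  if (!is.null(user_roi)) {
    stopifnot(inherits(user_roi, "body_roi"))
    return(user_roi)
  }
  opened <- .open_mask(mask, opening_um / pixel_size)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(opened * 1))))
  areas <- tabulate(lab[lab > 0])
  if (length(areas) == 0 || max(areas) * pixel_size^2 < min_body_area_um2)
    stop("no spheroid detected: no body-scale component in the actin mask")
  if (sum(areas * pixel_size^2 >= min_body_area_um2) > 1)
    warning("multiple body-scale components; largest selected")
  big <- which.max(areas)
  idx <- which(lab == big)
  rr <- (idx - 1) %% nrow(lab); cc <- (idx - 1) %/% nrow(lab)
  mx <- mean(cc); my <- mean(rr)
  u20 <- mean(cc^2) - mx^2; u02 <- mean(rr^2) - my^2
  u11 <- mean(cc * rr) - mx * my
  disc <- sqrt(((u20 - u02) / 2)^2 + u11^2)
  l1 <- (u20 + u02) / 2 + disc; l2 <- (u20 + u02) / 2 - disc
  # for a filled ellipse the second moments are a^2/4, b^2/4
  body_roi(center = c(mx, my),
           semiaxes = inflate * 2 * sqrt(c(l1, max(l2, 1e-9))),
           rotation = wrap_axial(rad2deg(0.5 * atan2(2 * u11, u20 - u02))))
}

#' Label outgrowths and flag contiguity with the body
#'
#' Removes the body-ellipse interior from the actin mask, labels the
#' remaining 8-connected components, and flags a component contiguous when
#' its mask, dilated by `r_c` pixels, reaches the body ellipse.
#'
#' @param mask actin mask.
#' @param body a [body_roi()].
#' @param r_c contiguity tolerance, px (bridges hairline segmentation gaps).
#' @return list: `labels` (integer matrix), `contiguous` (logical per
#'   label), `n`.
#' @export
segment_outgrowths <- function(mask, body, r_c = 2) {
  stopifnot(inherits(body, "body_roi"))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  rr <- (idx - 1) %% nr; cc <- (idx - 1) %/% nr
  inside <- in_ellipse(cc, rr, body$center, body$semiaxes, body$rotation)
  out <- mask
  out[idx[inside]] <- FALSE
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(out * 1))))
  n <- max(lab)
  contig <- logical(n)
  if (n > 0) {
    oidx <- which(lab > 0)
    orr <- (oidx - 1) %% nr; occ <- (oidx - 1) %/% nr
    d <- ellipse_distance(occ, orr, body$center, body$semiaxes, body$rotation)
    near <- d <= r_c
    if (any(near)) {
      tab <- unique(lab[oidx[near]])
      contig[tab] <- TRUE
    }
  }
  list(labels = lab, contiguous = contig, n = n)
}

#' Split and locate nuclei
#'
#' Distance-transform watershed splitting of a nuclei mask (tolerance
#' ~0.6 px, shallow enough to keep ~30%-overlapping pairs separate while
#' ignoring pixelation wiggle), returning one centroid per nucleus.
#'
#' @param mask nuclei mask (logical), from [preprocess_channel()].
#' @param pixel_size um/px.
#' @param nucleus_radius expected radius, um.
#' @param min_area_um2 minimum nucleus area.
#' @return data.frame: `nucleus`, `cx`, `cy` (px, 0-based). Zero rows for a
#'   blank mask.
#' @export
segment_nuclei <- function(mask, pixel_size = 0.5, nucleus_radius = 4,
                           min_area_um2 = 20) {
  lab <- .segment_nuclei_mask(mask, nucleus_radius / pixel_size,
                              min_area_um2, pixel_size)
  if (max(lab) == 0)
    return(data.frame(nucleus = integer(0), cx = numeric(0), cy = numeric(0)))
  mom <- .label_moments(lab)
  data.frame(nucleus = seq_len(nrow(mom)), cx = mom$cx, cy = mom$cy)
}

#' Assign nuclei to outgrowths and call migration phenotypes
#'
#' Nuclei inside the body ellipse are body nuclei. Each nucleus outside is
#' assigned to the outgrowth whose mask (dilated by `r_c`) contains it, or
#' to the nearest outgrowth mask within `max_assign_um`; ambiguous nuclei go
#' to the nearer mask. Phenotypes follow the contiguity rule: contiguous =
#' strand; disconnected with one nucleus = single, with several = cluster.
#'
#' @param outgrowths result of [segment_outgrowths()].
#' @param centroids data.frame from [segment_nuclei()].
#' @param body a [body_roi()].
#' @param pixel_size um/px.
#' @param r_c contiguity/assignment tolerance, px.
#' @param max_assign_um drop nuclei farther than this from every outgrowth.
#' @return list of class `outgrowth_records`: `outgrowths` data.frame
#'   (`outgrowth`, `contiguous`, `phenotype`, `n_nuclei`), `nuclei`
#'   data.frame (`outgrowth` = 0 for body nuclei, `cx`, `cy`), `labels`.
#' @export
classify_outgrowths <- function(outgrowths, centroids, body,
                                pixel_size = 0.5, r_c = 2,
                                max_assign_um = 15) {
  stopifnot(inherits(body, "body_roi"))
  lab <- outgrowths$labels
  nr <- nrow(lab)
  n_og <- outgrowths$n
  assign <- integer(nrow(centroids))
  if (nrow(centroids)) {
    inside <- in_ellipse(centroids$cx, centroids$cy, body$center,
                         body$semiaxes, body$rotation)
    px_lab <- lab[cbind(pmin(pmax(round(centroids$cy) + 1, 1), nr),
                        pmin(pmax(round(centroids$cx) + 1, 1), ncol(lab)))]
    assign <- ifelse(inside, 0L, px_lab)
    todo <- which(!inside & px_lab == 0L)
    if (length(todo) && n_og > 0) {
      oidx <- which(lab > 0)
      orr <- (oidx - 1) %% nr; occ <- (oidx - 1) %/% nr
      olab <- lab[oidx]
      for (i in todo) {
        d2 <- (occ - centroids$cx[i])^2 + (orr - centroids$cy[i])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) * pixel_size <= max_assign_um) assign[i] <- olab[j]
      }
    }
  }
  og <- data.frame(outgrowth = seq_len(n_og),
                   contiguous = outgrowths$contiguous,
                   n_nuclei = vapply(seq_len(n_og),
                                     function(k) sum(assign == k), 0L))
  og$phenotype <- ifelse(og$contiguous, "strand",
                         ifelse(og$n_nuclei <= 1, "single", "cluster"))
  structure(list(outgrowths = og,
                 nuclei = data.frame(outgrowth = assign, cx = centroids$cx,
                                     cy = centroids$cy),
                 labels = lab, body = body),
            class = "outgrowth_records")
}

#' Migration metrics for one spheroid
#'
#' Per-nucleus migration distance is the Euclidean distance from the
#' nucleus centroid to the nearest point of the body-ellipse boundary;
#' per-outgrowth maximal invasion depth is the maximum of that distance
#' over the outgrowth's mask pixels. Totals are stratified by contiguity.
#'
#' @param records an [classify_outgrowths()] result.
#' @param pixel_size um/px.
#' @param spheroid_id identifier carried into exports.
#' @return list of class `spheroid_result`: `body`, `outgrowths` (with
#'   `area_um2`, `total_distance_um`, `max_depth_um`), `nuclei` (with
#'   `dist_um`), `totals` (stratified data.frame), `mask` fields.
#' @export
migration_metrics <- function(records, pixel_size = 0.5, spheroid_id = 1L) {
  stopifnot(inherits(records, "outgrowth_records"))
  body <- records$body
  lab <- records$labels
  nr <- nrow(lab)
  og <- records$outgrowths
  nuc <- records$nuclei
  nuc$dist_um <- 0
  mig <- nuc$outgrowth > 0
  if (any(mig))
    nuc$dist_um[mig] <- ellipse_distance(nuc$cx[mig], nuc$cy[mig],
                                         body$center, body$semiaxes,
                                         body$rotation) * pixel_size
  n_og <- nrow(og)
  og$area_um2 <- og$max_depth_um <- og$total_distance_um <- rep(0, n_og)
  if (n_og > 0) {
    oidx <- which(lab > 0)
    orr <- (oidx - 1) %% nr; occ <- (oidx - 1) %/% nr
    olab <- lab[oidx]
    d <- ellipse_distance(occ, orr, body$center, body$semiaxes,
                          body$rotation) * pixel_size
    og$area_um2 <- vapply(seq_len(n_og),
                          function(k) sum(olab == k) * pixel_size^2, 0)
    og$max_depth_um <- vapply(seq_len(n_og),
                              function(k) max(c(0, d[olab == k])), 0)
    og$total_distance_um <- vapply(seq_len(n_og),
                                   function(k) sum(nuc$dist_um[nuc$outgrowth == k]), 0)
  }
  strat <- function(rows) data.frame(
    n_outgrowths = nrow(rows),
    n_migratory_cells = sum(rows$n_nuclei),
    total_migration_distance_um = sum(rows$total_distance_um),
    max_invasion_depth_um = if (nrow(rows)) max(rows$max_depth_um) else 0)
  totals <- rbind(
    cbind(stratum = "contiguous", strat(og[og$contiguous, , drop = FALSE])),
    cbind(stratum = "disconnected", strat(og[!og$contiguous, , drop = FALSE])),
    cbind(stratum = "all", strat(og)))
  structure(list(spheroid_id = spheroid_id, body = body, outgrowths = og,
                 nuclei = nuc, totals = totals, labels = lab),
            class = "spheroid_result")
}

#' @export
print.spheroid_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("spheroid_result %s: %d outgrowths (%d contiguous), ",
                     "%d migratory nuclei, total %.0f um, max depth %.0f um\n"),
              x$spheroid_id, t$n_outgrowths[3], t$n_outgrowths[1],
              t$n_migratory_cells[3], t$total_migration_distance_um[3],
              t$max_invasion_depth_um[3]))
  invisible(x)
}

#' Full migration analysis of one spheroid image pair
#'
#' Convenience wrapper: projection (if stacks), thresholding, body fit,
#' outgrowth labeling, nucleus splitting, phenotype calling and metrics.
#'
#' @param nuclei,actin channel images (2D or `[rows, cols, z]` stacks).
#' @param pixel_size um/px.
#' @param user_roi optional [body_roi()] override.
#' @param nucleus_radius um.
#' @param spheroid_id identifier.
#' @param ... passed to [segment_body()].
#' @return a [migration_metrics()] result, with the binarized actin mask
#'   attached as `actin_mask`.
#' @export
analyze_spheroid <- function(nuclei, actin, pixel_size = 0.5, user_roi = NULL,
                             nucleus_radius = 4, spheroid_id = 1L, ...) {
  nuclei <- project_stack(nuclei); actin <- project_stack(actin)
  stopifnot(identical(dim(nuclei), dim(actin)))
  nmask <- preprocess_channel(nuclei, pixel_size, 20)
  amask <- preprocess_channel(actin, pixel_size, 50)
  body <- segment_body(amask, pixel_size, user_roi = user_roi, ...)
  og <- segment_outgrowths(amask, body)
  cent <- segment_nuclei(nmask, pixel_size, nucleus_radius)
  rec <- classify_outgrowths(og, cent, body, pixel_size)
  res <- migration_metrics(rec, pixel_size, spheroid_id)
  res$actin_mask <- amask
  res
}

#' Aggregate spheroid results into a heatmap and rose histogram
#'
#' Translates each spheroid's binarized actin mask so its body center lands
#' at the canvas center (no rotation: all spheroids share the alignment
#' axis) and sums them pixelwise; bins the polar angle of every migratory
#' nucleus about its body center into `bin_width`-degree bins over 360.
#'
#' @param results list of [analyze_spheroid()] results (need `actin_mask`).
#' @param alignment_axis reference axis for [rose_axial_fraction()], deg.
#' @param bin_width rose bin width, degrees (divides 360).
#' @return list of class `population_aggregate`: `heatmap` (integer
#'   matrix), `rose` (data.frame `mid`, `count`), `angles` (all migratory
#'   nucleus angles, deg), `n_spheroids`, `alignment_axis`.
#' @export
aggregate_population <- function(results, alignment_axis = 0, bin_width = 10) {
  stopifnot(length(results) >= 1, 360 %% bin_width == 0)
  dims <- sapply(results, function(r) dim(r$labels))
  canvas <- c(2 * max(dims[1, ]) + 1, 2 * max(dims[2, ]) + 1)
  heat <- matrix(0L, canvas[1], canvas[2])
  cy0 <- (canvas[1] + 1) / 2; cx0 <- (canvas[2] + 1) / 2
  angles <- numeric(0)
  for (r in results) {
    m <- r$actin_mask
    if (is.null(m)) m <- r$labels > 0
    idx <- which(m)
    rr <- (idx - 1) %% nrow(m) + 1; cc <- (idx - 1) %/% nrow(m) + 1
    tr <- round(rr - (r$body$center[2] + 1) + cy0)
    tc <- round(cc - (r$body$center[1] + 1) + cx0)
    ok <- tr >= 1 & tr <= canvas[1] & tc >= 1 & tc <= canvas[2]
    ii <- cbind(tr[ok], tc[ok])
    heat[ii] <- heat[ii] + 1L
    mig <- r$nuclei[r$nuclei$outgrowth > 0, , drop = FALSE]
    if (nrow(mig))
      angles <- c(angles, rad2deg(atan2(mig$cy - r$body$center[2],
                                        mig$cx - r$body$center[1])))
  }
  nb <- as.integer(360 / bin_width)
  edges <- seq(-180, 180, by = bin_width)
  bin <- pmin(pmax(findInterval(angles, edges, rightmost.closed = TRUE), 1), nb)
  rose <- data.frame(mid = edges[-1] - bin_width / 2,
                     count = tabulate(bin, nb))
  structure(list(heatmap = heat, rose = rose, angles = angles,
                 n_spheroids = length(results),
                 alignment_axis = alignment_axis),
            class = "population_aggregate")
}

#' Fraction of migratory nuclei near the alignment axis
#'
#' Pools the two axial senses: the angular position of each migratory
#' nucleus is reduced to its axial distance from the alignment axis, and
#' the fraction within `half_width` degrees is returned.
#'
#' @param agg a [aggregate_population()] result.
#' @param half_width band half-width, degrees.
#' @return fraction in `[0, 1]`.
#' @export
rose_axial_fraction <- function(agg, half_width = 30) {
  stopifnot(inherits(agg, "population_aggregate"))
  if (length(agg$angles) == 0) return(NA_real_)
  mean(axial_distance(agg$angles, agg$alignment_axis) < half_width)
}

#' Plot a population rose histogram
#' @param x a `population_aggregate`.
#' @param ... unused.
#' @export
plot.population_aggregate <- function(x, ...) {
  th <- deg2rad(x$rose$mid)
  r <- x$rose$count / max(1, max(x$rose$count))
  plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = "migratory nuclei, angular position")
  for (i in seq_along(th)) {
    a <- seq(th[i] - deg2rad(5), th[i] + deg2rad(5), length.out = 8)
    graphics::polygon(c(0, r[i] * cos(a)), c(0, r[i] * sin(a)),
                      col = "grey60")
  }
  invisible(x)
}

#' Export spheroid results to a spreadsheet (CSV)
#'
#' One row per outgrowth with its index, phenotype, contiguity, migratory
#' cell count, area, migration distance and maximal depth, plus one totals
#' row per spheroid. The header carries `#`-prefixed comment lines
#' (seed/config hash if provided).
#'
#' @param results list of `spheroid_result` (or a single one).
#' @param path output CSV path.
#' @param header named character vector written as `# name: value` lines.
#' @return the exported data.frame, invisibly.
#' @export
export_results <- function(results, path, header = NULL) {
  if (inherits(results, "spheroid_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    og <- r$outgrowths
    t <- r$totals[r$totals$stratum == "all", ]
    main <- if (nrow(og)) data.frame(
      spheroid_id = r$spheroid_id, outgrowth_index = og$outgrowth,
      phenotype = og$phenotype, contiguous = og$contiguous,
      n_migratory_cells = og$n_nuclei, area_um2 = og$area_um2,
      migration_distance_um = og$total_distance_um,
      max_depth_um = og$max_depth_um) else NULL
    tot <- data.frame(
      spheroid_id = r$spheroid_id, outgrowth_index = NA_integer_,
      phenotype = "total", contiguous = NA,
      n_migratory_cells = t$n_migratory_cells, area_um2 = sum(og$area_um2),
      migration_distance_um = t$total_migration_distance_um,
      max_depth_um = t$max_invasion_depth_um)
    rbind(main, tot)
  })
  df <- do.call(rbind, rows)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop(sprintf("export_results: cannot write '%s'", path))
  on.exit(close(con))
  for (nm in names(header))
    writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
  write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Re-read an exported results table
#' @param path CSV written by [export_results()].
#' @return data.frame (comment header lines skipped).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_results: no such file '%s'", path))
  read.csv(path, comment.char = "#")
}
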