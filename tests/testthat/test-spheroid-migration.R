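scene_and_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- generate_spheroid_scene(random_spheroid_spec(
        seed = 31, n_strands = 3, n_clusters = 2, n_singles = 3,
        min_direction_sep = 18))
      res <- analyze_spheroid(sc$nuclei, sc$actin, 0.5)
      cache <<- list(sc = sc, res = res)
    }
    cache
  }
})

test_that("stack projection is a per-channel maximum", {
  a <- array(0, c(6, 5, 3)); a[2, 2, 1] <- 1; a[5, 4, 3] <- 2
  p <- project_stack(a)
  expect_equal(dim(p), c(6, 5))
  expect_equal(p[2, 2], 1); expect_equal(p[5, 4], 2)
  # single plane: identity; 2D passthrough
  expect_equal(project_stack(a[, , 1, drop = FALSE]), a[, , 1])
  expect_identical(project_stack(p), p)
  # channel shape mismatch
  expect_error(project_stack(list(a, array(0, c(4, 5, 3)))), "differ in shape")
  # projection of a generated scene's own z-replicated stack equals the scene
  sc <- scene_and_result()$sc
  st <- array(0, c(dim(sc$actin), 2))
  st[, , 1] <- sc$actin / 2; st[, , 2] <- sc$actin
  expect_equal(project_stack(st), sc$actin)
})

test_that("channel preprocessing removes sub-threshold specks", {
  img <- fibermag:::blank_image(c(120, 120))
  img <- fibermag:::draw_disk(img, 30, 30, 1.5)     # ~7 px^2 -> 1.8 um^2
  img <- fibermag:::draw_disk(img, 80, 80, 16)      # ~800 px^2 -> 200 um^2
  m <- preprocess_channel(img, 0.5, min_object_area = 20)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  expect_equal(max(lab), 1)
  expect_true(m[81, 81]); expect_false(m[31, 31])
  expect_false(any(preprocess_channel(matrix(0, 50, 50), 0.5)))
})

test_that("body ellipse fit recovers the generated body; user ROI wins", {
  x <- scene_and_result()
  amask <- preprocess_channel(x$sc$actin, 0.5, 50)
  fit <- segment_body(amask, 0.5)
  expect_lt(sqrt(sum((fit$center - x$sc$body$center)^2)), 5)
  expect_equal(sort(fit$semiaxes), sort(1.05 * x$sc$body$semiaxes),
               tolerance = 0.1)
  roi <- body_roi(c(100, 100), c(30, 20), 15)
  expect_identical(segment_body(amask, 0.5, user_roi = roi), roi)
  expect_error(segment_body(matrix(FALSE, 64, 64), 0.5), "no spheroid")
})

test_that("outgrowth contiguity follows the dilation rule", {
  body <- body_roi(c(100, 100), c(40, 30), 0)
  mask <- matrix(FALSE, 200, 200)
  mask[101, 60:141] <- TRUE                       # crosses the body
  mask[101, 143:160] <- TRUE                      # 2 px gap: contiguous at r_c = 2
  mask[50:55, 50:55] <- TRUE                      # far away: disconnected
  og <- segment_outgrowths(mask, body)
  expect_equal(og$n, 3)
  d <- vapply(seq_len(og$n), function(k) {
    idx <- which(og$labels == k)
    rr <- (idx - 1) %% 200; cc <- (idx - 1) %/% 200
    min(ellipse_distance(cc, rr, body$center, body$semiaxes, body$rotation))
  }, numeric(1))
  expect_equal(og$contiguous, d <= 2)
  expect_equal(sum(og$contiguous), 2)
})

test_that("watershed splits overlapping nuclei", {
  img <- fibermag:::blank_image(c(120, 120))
  img <- fibermag:::draw_disk(img, 50, 60, 8)
  img <- fibermag:::draw_disk(img, 61, 60, 8)     # ~30% area overlap
  cent <- segment_nuclei(img > 0.5, 0.5, nucleus_radius = 4)
  expect_equal(nrow(cent), 2)
  # isolated nucleus: one centroid within 2 px of truth
  img2 <- fibermag:::draw_disk(fibermag:::blank_image(c(80, 80)), 40, 35, 7)
  c2 <- segment_nuclei(img2 > 0.5, 0.5)
  expect_equal(nrow(c2), 1)
  expect_lt(sqrt((c2$cx - 40)^2 + (c2$cy - 35)^2), 2)
  expect_equal(nrow(segment_nuclei(matrix(FALSE, 50, 50), 0.5)), 0)
})

test_that("phenotype calling follows the contiguity/nucleus-count rule", {
  x <- scene_and_result()
  res <- x$res; tr <- x$sc$truth
  og <- res$outgrowths
  expect_true(all(og$phenotype[og$contiguous] == "strand"))
  expect_true(all(og$phenotype[!og$contiguous & og$n_nuclei == 1] == "single"))
  expect_true(all(og$phenotype[!og$contiguous & og$n_nuclei > 1] == "cluster"))
  # class composition matches the generated truth
  cls_map <- c(contiguous_strand = "strand", disconnected_cluster = "cluster",
               disconnected_single = "single")
  expect_equal(as.vector(table(factor(og$phenotype, levels = cls_map))),
               as.vector(table(factor(cls_map[tr$outgrowths$class],
                                      levels = cls_map))))
  # nucleus conservation: body + outgrowth nuclei = all detected (exact)
  expect_equal(sum(res$nuclei$outgrowth == 0) + sum(og$n_nuclei),
               nrow(res$nuclei))
})

test_that("migration metrics track truth distances and are unit-consistent", {
  x <- scene_and_result()
  res <- x$res; tr <- x$sc$truth
  t_all <- function(t) t[t$stratum == "all", ]
  expect_equal(t_all(res$totals)$n_migratory_cells,
               t_all(tr$totals)$n_migratory_cells)
  expect_lt(abs(t_all(res$totals)$total_migration_distance_um /
                t_all(tr$totals)$total_migration_distance_um - 1), 0.15)
  expect_lt(abs(t_all(res$totals)$max_invasion_depth_um /
                t_all(tr$totals)$max_invasion_depth_um - 1), 0.05)
  # a nucleus on the (fitted) boundary has distance 0
  body <- res$body
  bp <- ellipse_ray_point(body$center, body$semiaxes, body$rotation, 30)
  expect_lt(ellipse_distance(bp[1], bp[2], body$center, body$semiaxes,
                             body$rotation) * 0.5, 1e-6)
  # doubling pixel size with coordinates halved leaves um metrics unchanged
  rec <- classify_outgrowths(
    segment_outgrowths(preprocess_channel(x$sc$actin, 0.5, 50), body),
    segment_nuclei(preprocess_channel(x$sc$nuclei, 0.5, 20), 0.5, 4),
    body, pixel_size = 0.5)
  m1 <- migration_metrics(rec, pixel_size = 0.5)
  half <- rec
  half$nuclei$cx <- half$nuclei$cx / 2; half$nuclei$cy <- half$nuclei$cy / 2
  half$body <- body_roi(body$center / 2, body$semiaxes / 2, body$rotation)
  # labels stay at native resolution for mask metrics; compare nucleus sums
  m2 <- migration_metrics(half, pixel_size = 1.0)
  expect_equal(sum(m2$nuclei$dist_um), sum(m1$nuclei$dist_um),
               tolerance = 1e-9)
})

test_that("population aggregation sums masks and conserves rose counts", {
  x <- scene_and_result()
  res <- x$res
  agg1 <- aggregate_population(list(res))
  expect_equal(max(agg1$heatmap), 1)
  expect_equal(sum(agg1$heatmap), sum(res$actin_mask))
  expect_equal(sum(agg1$rose$count),
               sum(res$nuclei$outgrowth > 0))
  agg2 <- aggregate_population(list(res, res))
  expect_equal(max(agg2$heatmap), 2)
  expect_equal(sum(agg2$rose$count), 2 * sum(res$nuclei$outgrowth > 0))
  expect_true(is.finite(rose_axial_fraction(agg2)))
})

test_that("exported spreadsheets round-trip the in-memory records", {
  x <- scene_and_result()
  res <- x$res
  path <- tempfile(fileext = ".csv")
  df <- export_results(res, path, header = c(seed = 31))
  back <- read_results(path)
  expect_equal(nrow(back), nrow(res$outgrowths) + 1)
  expect_equal(back$n_migratory_cells, df$n_migratory_cells)
  # totals row equals column sums of the outgrowth rows
  main <- back[!is.na(back$outgrowth_index), ]
  tot <- back[is.na(back$outgrowth_index), ]
  expect_equal(tot$n_migratory_cells, sum(main$n_migratory_cells))
  expect_equal(tot$migration_distance_um, sum(main$migration_distance_um),
               tolerance = 1e-6)
  # zero outgrowths: totals row only
  sc0 <- generate_spheroid_scene(spheroid_scene_spec(
    body = list(center = c(256, 256), semiaxes = c(100, 80), n_nuclei = 30L),
    image_shape = c(512, 512), seed = 2))
  res0 <- analyze_spheroid(sc0$nuclei, sc0$actin, 0.5, spheroid_id = 99)
  p0 <- tempfile(fileext = ".csv")
  export_results(res0, p0)
  b0 <- read_results(p0)
  expect_equal(nrow(b0[b0$spheroid_id == 99 & is.na(b0$outgrowth_index), ]), 1)
  suppressWarnings(
    expect_error(export_results(res, "/nonexistent-dir/x/y.csv"),
                 "cannot write"))
})
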