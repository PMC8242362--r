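simple_spec <- function(outgrowths, seed = 1, ...) {
  spheroid_scene_spec(
    body = list(center = c(512, 512), semiaxes = c(170, 140), rotation = 20,
                n_nuclei = 40L),
    outgrowths = outgrowths, seed = seed, ...)
}

test_that("spec validation enforces the class invariants", {
  bad_single <- data.frame(class = "disconnected_single", direction = 0,
                           path_length = 25, n_nuclei = 2, gap_to_body = 20)
  expect_error(simple_spec(bad_single), "exactly 1 nucleus")
  bad_strand <- data.frame(class = "contiguous_strand", direction = 0,
                           path_length = 100, n_nuclei = 3, gap_to_body = 10)
  expect_error(simple_spec(bad_strand), "gap_to_body")
  bad_cluster <- data.frame(class = "disconnected_cluster", direction = 0,
                            path_length = 30, n_nuclei = 1, gap_to_body = 20)
  expect_error(simple_spec(bad_cluster), ">= 2")
})

test_that("a scene with no outgrowths is body-only with zero totals", {
  sc <- generate_spheroid_scene(simple_spec(NULL))
  t <- sc$truth$totals
  expect_true(all(t$n_outgrowths == 0))
  expect_true(all(t$n_migratory_cells == 0))
  expect_true(all(t$total_migration_distance_um == 0))
  # actin support is exactly the body ellipse raster
  idx <- which(sc$support$actin)
  rr <- (idx - 1) %% nrow(sc$support$actin)
  cc <- (idx - 1) %/% nrow(sc$support$actin)
  d <- ellipse_distance(cc, rr, sc$body$center, sc$body$semiaxes,
                        sc$body$rotation)
  expect_lt(max(d), 1.5)   # support never leaves the body by more than AA edge
})

test_that("outgrowth construction matches the requested composition", {
  og <- data.frame(
    class = c(rep("contiguous_strand", 4), rep("disconnected_cluster", 2),
              rep("disconnected_single", 3)),
    direction = c(0, 80, 160, 240, 40, 200, 120, 280, 320),
    path_length = c(rep(100, 4), rep(30, 2), rep(25, 3)),
    n_nuclei = c(3, 3, 4, 3, 3, 3, 1, 1, 1),
    gap_to_body = c(rep(0, 4), rep(20, 2), rep(25, 3)))
  sc <- generate_spheroid_scene(simple_spec(og, seed = 9))
  tr <- sc$truth
  expect_equal(nrow(tr$outgrowths), 9)
  t_all <- tr$totals[tr$totals$stratum == "all", ]
  expect_equal(t_all$n_migratory_cells, sum(og$n_nuclei))  # 13 + 6 + 3
  # totals equal column sums, per stratum
  for (s in c("contiguous", "disconnected")) {
    rows <- tr$outgrowths[tr$outgrowths$contiguous == (s == "contiguous"), ]
    t_s <- tr$totals[tr$totals$stratum == s, ]
    expect_equal(t_s$n_migratory_cells, sum(rows$n_nuclei))
    expect_equal(t_s$total_migration_distance_um, sum(rows$total_distance_um))
  }
  # every generated nucleus appears exactly once
  expect_equal(nrow(tr$nuclei), 40 + sum(og$n_nuclei))
  expect_equal(sum(tr$nuclei$outgrowth > 0), sum(og$n_nuclei))
  # migratory nuclei lie outside the body; distances positive
  mig <- tr$nuclei[tr$nuclei$outgrowth > 0, ]
  expect_true(all(mig$dist_um > 0))
  expect_false(any(in_ellipse(mig$cx, mig$cy, sc$body$center,
                              sc$body$semiaxes, sc$body$rotation)))
  # disconnected outgrowth supports keep the declared gap from the body
  body_only <- generate_spheroid_scene(simple_spec(NULL, seed = 9))
  for (k in which(!tr$outgrowths$contiguous)) {
    og_sc <- generate_spheroid_scene(simple_spec(og[k, ], seed = 9))
    sup <- og_sc$support$actin & !body_only$support$actin
    idx <- which(sup)
    rr <- (idx - 1) %% 1024; cc <- (idx - 1) %/% 1024
    d <- ellipse_distance(cc, rr, og_sc$body$center, og_sc$body$semiaxes,
                          og_sc$body$rotation)
    expect_gte(min(d) * 0.5, og$gap_to_body[k] - 1)   # px -> um at 0.5 um/px
  }
  # max depth dominates every per-nucleus distance
  for (k in seq_len(9)) {
    nd <- tr$nuclei$dist_um[tr$nuclei$outgrowth == k]
    expect_gte(tr$outgrowths$max_depth_um[k] + 1e-9, max(nd))
  }
})

test_that("scenes are seed-deterministic and bounded by the canvas", {
  s1 <- generate_spheroid_scene(random_spheroid_spec(seed = 21))
  s2 <- generate_spheroid_scene(random_spheroid_spec(seed = 21))
  expect_identical(s1$nuclei, s2$nuclei)
  expect_identical(s1$truth$outgrowths, s2$truth$outgrowths)
  # an outgrowth pushed past the canvas edge raises an explicit error
  og <- data.frame(class = "contiguous_strand", direction = 0,
                   path_length = 400, n_nuclei = 3, gap_to_body = 0)
  expect_error(generate_spheroid_scene(simple_spec(og)), "larger canvas")
})

test_that("outgrowth directions follow the axial concentration", {
  dirs <- unlist(lapply(1:12, function(i)
    random_spheroid_spec(seed = i, direction_kappa = 6)$outgrowths$direction))
  frac <- mean(axial_distance(dirs, 0) < 30)
  p <- axial_band_oracle(6, 30)
  expect_gt(frac, p - 3 * sqrt(p * (1 - p) / length(dirs)))
})
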