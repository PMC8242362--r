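# validation benchmarks on synthetic scenes with known ground truth
#
# These runners define the package's reference study conditions (scene
# sizes, fiber counts, replicate numbers) and are used both by the test
# suite and by scripts/acceptance.R. Scene seeds are derived from a single
# base seed so whole benchmarks are reproducible.

#' Anisotropy score versus generator alignment
#'
#' Generates replicate fiber scenes across a ladder of axial concentrations
#' and scores each with [anisotropy_score()]; the mean score must rise from
#' ~0 (isotropic) to ~1 (parallel) with kappa.
#'
#' @param kappas axial von Mises concentrations.
#' @param n_seeds replicate scenes per kappa.
#' @param n_fibers fibers per scene; the default keeps the finite-sample
#'   score under isotropy (~ sqrt(pi / 4 n_eff)) well below 0.05.
#' @param seed base seed.
#' @return data.frame: `kappa`, `mean_score`, `sd_score`.
#' @export
benchmark_anisotropy <- function(kappas = c(0, 1, 2, 4, 8, 1e6),
                                 n_seeds = 5, n_fibers = 700, seed = 1L) {
  rows <- lapply(seq_along(kappas), function(i) {
    scores <- vapply(seq_len(n_seeds), function(j) {
      sc <- generate_fiber_image(fiber_field_spec(
        image_shape = c(1400, 1400), n_fibers = n_fibers,
        length_model = length_model_unmasked(),
        orientation_kappa = kappas[i],
        seed = seed + 1000L * i + j))
      anisotropy_score(sc$image)$score
    }, numeric(1))
    data.frame(kappa = kappas[i], mean_score = mean(scores),
               sd_score = sd(scores))
  })
  do.call(rbind, rows)
}

#' Fiber length and diameter recovery
#'
#' Renders fibers from a length model over enough non-overlapping scenes to
#' accumulate `n_total` fibers, measures them with [measure_fibers()], and
#' compares the measured means with the generated truth.
#'
#' @param length_model a `length_model`.
#' @param n_total total fibers to accumulate (>= 500 for stable means).
#' @param per_scene fibers per scene (placement stays feasible).
#' @param image_px square scene side, px (must hold the longest fiber).
#' @param seed base seed.
#' @return list: `truth_mean_um`, `measured_mean_um`, `measured_mean_diameter_um`,
#'   `n_measured`, `rel_error` (lengths, signed).
#' @export
benchmark_fiber_length <- function(length_model, n_total = 500,
                                   per_scene = 84, image_px = 1024,
                                   seed = 1L) {
  n_scenes <- ceiling(n_total / per_scene)
  truth <- meas <- diam <- numeric(0)
  for (s in seq_len(n_scenes)) {
    sc <- NULL
    for (try in 0:4) {   # deterministic reseed if a packing run jams
      sc <- tryCatch(generate_fiber_image(fiber_field_spec(
        image_shape = c(image_px, image_px), n_fibers = per_scene,
        length_model = length_model, orientation_kappa = 2,
        overlap = FALSE, seed = seed + s + 9973L * try)),
        error = function(e) NULL)
      if (!is.null(sc)) break
    }
    if (is.null(sc)) stop("fiber placement failed after 5 reseeds")
    m <- measure_fibers(sc$image, sc$spec$pixel_size)
    truth <- c(truth, sc$fibers$length_um)
    meas <- c(meas, m$length_um)
    diam <- c(diam, m$diameter_um)
  }
  list(truth_mean_um = mean(truth), measured_mean_um = mean(meas),
       measured_mean_diameter_um = mean(diam), n_measured = length(meas),
       rel_error = mean(meas) / mean(truth) - 1)
}

#' FWHM of measured cell orientations versus generator alignment
#'
#' Generates replicate tenocyte scenes per kappa, measures per-cell
#' orientations with [segment_cells()], and records the FWHM of each
#' scene's axial orientation histogram as well as the FWHM of the angles
#' pooled over the replicates (a steadier ladder statistic).
#'
#' @param kappas axial concentrations.
#' @param n_seeds replicate scenes per kappa.
#' @param n_cells cells per scene.
#' @param seed base seed.
#' @return data.frame: `kappa`, `mean_fwhm`, `sd_fwhm`, `pooled_fwhm`.
#' @export
benchmark_fwhm <- function(kappas = c(0.5, 1, 2, 4, 8), n_seeds = 5,
                           n_cells = 80, seed = 1L) {
  rows <- lapply(seq_along(kappas), function(i) {
    angles <- vector("list", n_seeds)
    fw <- vapply(seq_len(n_seeds), function(j) {
      sc <- generate_tenocyte_image(n_cells, orientation_kappa = kappas[i],
                                    image_shape = c(1024, 1024),
                                    seed = seed + 1000L * i + j)
      cells <- segment_cells(sc$image, sc$pixel_size)
      angles[[j]] <<- cells$orientation
      orientation_histogram(cells$orientation)$fwhm
    }, numeric(1))
    data.frame(kappa = kappas[i], mean_fwhm = mean(fw), sd_fwhm = sd(fw),
               pooled_fwhm = orientation_histogram(unlist(angles))$fwhm)
  })
  do.call(rbind, rows)
}

#' Spheroid-migration recovery benchmark
#'
#' Generates `n` spheroid scenes (mixed outgrowth classes, directions kept
#' apart so components stay distinct), runs the full migration pipeline on
#' each, and aggregates recovery errors against ground truth.
#'
#' @param n scenes.
#' @param direction_kappa outgrowth direction concentration.
#' @param n_strands,n_clusters,n_singles outgrowths per scene.
#' @param seed base seed.
#' @return list with `per_scene` (data.frame) and summary fields:
#'   `count_rel_error`, `distance_rel_error`, `depth_rel_error` (signed,
#'   on condition totals/means), `phenotype_accuracy`,
#'   `conservation_exact` (logical), `results` (list of `spheroid_result`).
#' @export
benchmark_spheroid_recovery <- function(n = 25, direction_kappa = 0,
                                        n_strands = 3, n_clusters = 2,
                                        n_singles = 3, seed = 1L) {
  per <- vector("list", n)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_spheroid_scene(random_spheroid_spec(
      seed = seed + i, direction_kappa = direction_kappa,
      n_strands = n_strands, n_clusters = n_clusters, n_singles = n_singles,
      min_direction_sep = 18))
    res <- analyze_spheroid(sc$nuclei, sc$actin, sc$spec$pixel_size,
                            spheroid_id = i)
    results[[i]] <- res
    tt <- sc$truth$totals; mt <- res$totals
    all_t <- function(t, col) t[t$stratum == "all", col]
    # phenotype multiset agreement (components are well separated)
    cls_map <- c(contiguous_strand = "strand", disconnected_cluster = "cluster",
                 disconnected_single = "single")
    truth_cls <- table(factor(cls_map[sc$truth$outgrowths$class],
                              levels = c("strand", "cluster", "single")))
    meas_cls <- table(factor(res$outgrowths$phenotype,
                             levels = c("strand", "cluster", "single")))
    nuc_det <- nrow(res$nuclei)
    per[[i]] <- data.frame(
      scene = i,
      truth_cells = all_t(tt, "n_migratory_cells"),
      meas_cells = all_t(mt, "n_migratory_cells"),
      truth_dist = all_t(tt, "total_migration_distance_um"),
      meas_dist = all_t(mt, "total_migration_distance_um"),
      truth_depth = all_t(tt, "max_invasion_depth_um"),
      meas_depth = all_t(mt, "max_invasion_depth_um"),
      truth_disc_cells = tt[tt$stratum == "disconnected", "n_migratory_cells"],
      meas_disc_cells = mt[mt$stratum == "disconnected", "n_migratory_cells"],
      n_outgrowths_truth = nrow(sc$truth$outgrowths),
      phenotype_matched = sum(pmin(truth_cls, meas_cls)),
      conserved = sum(res$nuclei$outgrowth == 0) +
        sum(res$outgrowths$n_nuclei) == nuc_det)
  }
  per <- do.call(rbind, per)
  list(per_scene = per,
       count_rel_error = sum(per$meas_cells) / sum(per$truth_cells) - 1,
       distance_rel_error = sum(per$meas_dist) / sum(per$truth_dist) - 1,
       depth_rel_error = mean(per$meas_depth) / mean(per$truth_depth) - 1,
       phenotype_accuracy = sum(per$phenotype_matched) /
         sum(per$n_outgrowths_truth),
       conservation_exact = all(per$conserved),
       results = results)
}

#' Directional bias of migratory nuclei
#'
#' Generates `n` spheroid scenes with the given outgrowth-direction
#' concentration (directions drawn faithfully, no separation constraint),
#' analyzes them, aggregates the population, and returns the rose-plot
#' fraction of migratory nuclei within 30 degrees (axially) of the
#' alignment axis, alongside the generator's analytic expectation.
#'
#' @param n scenes.
#' @param direction_kappa axial concentration (0 = uniform).
#' @param seed base seed.
#' @return list: `fraction`, `expected` (quadrature of the axial density),
#'   `n_nuclei`, `aggregate`.
#' @export
benchmark_direction_bias <- function(n = 25, direction_kappa = 6, seed = 1L) {
  results <- lapply(seq_len(n), function(i) {
    sc <- generate_spheroid_scene(random_spheroid_spec(
      seed = seed + i, direction_kappa = direction_kappa))
    analyze_spheroid(sc$nuclei, sc$actin, sc$spec$pixel_size, spheroid_id = i)
  })
  agg <- aggregate_population(results, alignment_axis = 0)
  list(fraction = rose_axial_fraction(agg, 30),
       expected = axial_band_probability(direction_kappa, 30),
       n_nuclei = length(agg$angles), aggregate = agg)
}
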