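# configuration-driven entry point shared by all modules
#
# A run configuration is a plain named list (typically read from a YAML
# file) with a `command` ("generate", "field" or "analyze"), a `mode`
# where the command has several, a `seed`, an output directory and
# documented per-module overrides. `run_config()` validates, dispatches,
# and writes a JSON manifest (config echo, seed, hash, versions, timing)
# beside the outputs so any run can be reproduced bit for bit.

.RUN_DEFAULTS <- list(
  generate = list(
    fibers = list(n_fibers = 150, orientation_kappa = 2, mean_axis = 0,
                  diameter_mean = 2, length_mean = 90, pixel_size = 0.5,
                  image_shape = c(1024, 1024), n_scenes = 1),
    tenocytes = list(n_cells = 80, orientation_kappa = 4, aspect_ratio = 4,
                     mean_axis = 0, pixel_size = 0.5, n_scenes = 1),
    viability = list(n_nuclei = 400, dead_fraction = 0.25, pixel_size = 0.5,
                     n_scenes = 1),
    spheroids = list(direction_kappa = 0, n_strands = 3, n_clusters = 2,
                     n_singles = 3, pixel_size = 0.5, n_scenes = 1)),
  field = list(
    profile = list(spacing_cm = 6, radius_cm = 1.905, length_cm = 3.81,
                   surface_mT = 661.9, n_points = 201),
    slice = list(spacing_cm = 6, radius_cm = 1.905, length_cm = 3.81,
                 surface_mT = 661.9, n_grid = 81)),
  analyze = list(
    fibers = list(pixel_size = 0.5, roi = "full"),
    cells = list(pixel_size = 0.5, mode2 = "orientation", bin_width = 10,
                 reference_axis = 0),
    spheroids = list(pixel_size = 0.5, axis_deg = 0, nucleus_radius = 4)))

# merge overrides into mode defaults, rejecting unknown keys
.merge_config <- function(command, mode, overrides) {
  defs <- .RUN_DEFAULTS[[command]][[mode]]
  if (is.null(defs))
    stop(sprintf("unknown command/mode '%s %s'", command, mode))
  extra <- setdiff(names(overrides), names(defs))
  if (length(extra))
    stop(sprintf("unknown option(s) for '%s %s': %s", command, mode,
                 paste(extra, collapse = ", ")))
  modifyList(defs, overrides)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with fields `command`, `mode`, `seed`, `out` and
#'   optional per-mode overrides under `options`.
#' @param flags named list of command-line style overrides; flags win over
#'   the file.
#' @return validated config list.
#' @export
read_run_config <- function(path, flags = list()) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  cfg <- yaml::read_yaml(path)
  cfg$options <- modifyList(cfg$options %||% list(),
                            flags$options %||% list())
  for (nm in setdiff(names(flags), "options")) cfg[[nm]] <- flags[[nm]]
  cfg
}

#' Execute a run configuration
#'
#' Dispatches to the generator, magnetics or analysis modules and writes
#' all artifacts plus a `manifest.json` into `config$out`.
#'
#' @param config list with `command` (`"generate"`, `"field"`,
#'   `"analyze"`), `mode` (e.g. `"fibers"`), `seed`, `out` (directory),
#'   optional `input` (file/dir for analyze) and `options` (named
#'   overrides of the documented defaults).
#' @return list of written paths, invisibly.
#' @export
run_config <- function(config) {
  t0 <- Sys.time()
  stopifnot(is.list(config), !is.null(config$command), !is.null(config$mode))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opt <- .merge_config(config$command, config$mode, config$options %||% list())
  paths <- switch(config$command,
    generate = .run_generate(config$mode, opt, seed, out_dir),
    field = .run_field(config$mode, opt, out_dir),
    analyze = .run_analyze(config$mode, opt, config$input, out_dir),
    stop(sprintf("unknown command '%s'", config$command)))
  manifest <- list(config = config, options = opt, seed = seed,
                   config_hash = config_hash(list(config, opt)),
                   package = as.character(packageVersion("fibermag")),
                   r_version = R.version.string,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   outputs = unname(unlist(paths)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, manifest = mpath))
}

.run_generate <- function(mode, opt, seed, out_dir) {
  lapply(seq_len(opt$n_scenes), function(i) {
    s <- seed + (i - 1L)    # child seed per scene index
    scene <- switch(mode,
      fibers = generate_fiber_image(fiber_field_spec(
        image_shape = opt$image_shape, pixel_size = opt$pixel_size,
        n_fibers = opt$n_fibers, diameter_mean = opt$diameter_mean,
        length_model = length_model_masked(opt$length_mean),
        orientation_kappa = opt$orientation_kappa,
        mean_axis = opt$mean_axis, seed = s)),
      tenocytes = generate_tenocyte_image(
        n_cells = opt$n_cells, orientation_kappa = opt$orientation_kappa,
        aspect_ratio = opt$aspect_ratio, mean_axis = opt$mean_axis,
        pixel_size = opt$pixel_size, seed = s),
      viability = generate_viability_image(
        n_nuclei = opt$n_nuclei, dead_fraction = opt$dead_fraction,
        pixel_size = opt$pixel_size, seed = s),
      spheroids = generate_spheroid_scene(random_spheroid_spec(
        seed = s, direction_kappa = opt$direction_kappa,
        n_strands = opt$n_strands, n_clusters = opt$n_clusters,
        n_singles = opt$n_singles, pixel_size = opt$pixel_size)),
      stop(sprintf("unknown generate mode '%s'", mode)))
    write_scene(scene, out_dir, sprintf("%s_%03d", mode, i))
  })
}

.run_field <- function(mode, opt, out_dir) {
  m <- cyl_magnet(R = opt$radius_cm / 100, L = opt$length_cm / 100,
                  surface_field = opt$surface_mT / 1000)
  pair <- magnet_pair(m, opt$spacing_cm / 100)
  if (mode == "profile") {
    h <- pair$d / 2
    z <- seq(-h, h, length.out = opt$n_points)
    prof <- pair_axial_profile(pair, z)
    p <- file.path(out_dir, "profile.csv")
    write_csv_commented(prof, p, c(spacing_cm = opt$spacing_cm))
    list(p)
  } else {
    ext <- pair$d / 2 + m$L
    sl <- field_slice(pair, x = seq(-2 * m$R, 2 * m$R, length.out = opt$n_grid),
                      z = seq(-0.99 * pair$d / 2, 0.99 * pair$d / 2,
                              length.out = opt$n_grid))
    p <- file.path(out_dir, "slice_B_T.csv")
    write.csv(sl$B, p, row.names = FALSE)
    png_path <- file.path(out_dir, "slice.png")
    grDevices::png(png_path, 640, 640)
    plot(sl)
    grDevices::dev.off()
    list(p, png_path)
  }
}

.run_analyze <- function(mode, opt, input, out_dir) {
  if (is.null(input) || !all(file.exists(input)))
    stop(sprintf("analyze: input not found: '%s'",
                 paste(input %||% "<missing>", collapse = ", ")))
  if (mode == "fibers") {
    st <- read_stack(input, opt$pixel_size)
    img <- st$channels[[1]]
    roi <- NULL
    if (!identical(opt$roi, "full")) {
      rc <- as.numeric(strsplit(opt$roi, ",")[[1]])  # x0,y0,x1,y1
      roi <- matrix(FALSE, nrow(img), ncol(img))
      roi[(rc[2]:rc[4]) + 1, (rc[1]:rc[3]) + 1] <- TRUE
    }
    a <- anisotropy_score(img, roi)
    meas <- measure_fibers(img, opt$pixel_size)
    p1 <- file.path(out_dir, "fiber_measurements.csv")
    write_csv_commented(as.data.frame(meas), p1, c(input = input))
    p2 <- file.path(out_dir, "fiber_summary.csv")
    write_csv_commented(data.frame(
      anisotropy = a$score, mean_orientation = a$mean_orientation,
      n_fibers = nrow(meas), mean_length_um = mean(meas$length_um),
      mean_diameter_um = mean(meas$diameter_um)), p2, c(input = input))
    p3 <- file.path(out_dir, "orientation_map.png")
    rgb <- orientation_rgb(orientation_map(img), img)
    EBImage::writeImage(EBImage::Image(aperm(rgb, c(2, 1, 3)),
                                       colormode = "Color"), p3)
    list(p1, p2, p3)
  } else if (mode == "cells") {
    st <- read_stack(input, opt$pixel_size)
    if (identical(opt$mode2, "viability")) {
      if (st$n_channels < 2) stop("viability analysis needs 2 channels")
      v <- viability(st$channels[[1]], st$channels[[2]], opt$pixel_size)
      p <- file.path(out_dir, "viability.csv")
      write_csv_commented(data.frame(n_total = v$n_total,
                                     n_pi_positive = v$n_pi_positive,
                                     percent_dead = v$percent_dead), p,
                          c(input = input))
      list(p)
    } else {
      cells <- segment_cells(st$channels[[1]], opt$pixel_size)
      oh <- orientation_histogram(cells$orientation, opt$bin_width,
                                  opt$reference_axis)
      p1 <- file.path(out_dir, "cells.csv")
      write_csv_commented(as.data.frame(cells), p1, c(input = input))
      p2 <- file.path(out_dir, "orientation_summary.csv")
      write_csv_commented(data.frame(
        n = oh$n, fwhm_deg = oh$fwhm,
        frac_0_30 = oh$band_fractions[["0-30"]],
        frac_30_60 = oh$band_fractions[["30-60"]],
        frac_60_90 = oh$band_fractions[["60-90"]]), p2, c(input = input))
      list(p1, p2)
    }
  } else if (mode == "spheroids") {
    files <- if (dir.exists(input))
      list.files(input, pattern = "\\.tiff?$", full.names = TRUE) else input
    if (length(files) == 0) stop(sprintf("analyze: no TIFFs in '%s'", input))
    results <- lapply(seq_along(files), function(i) {
      st <- read_stack(files[i], opt$pixel_size)
      if (st$n_channels < 2) stop(sprintf("'%s': need 2 channels", files[i]))
      analyze_spheroid(st$channels[[1]], st$channels[[2]], opt$pixel_size,
                       nucleus_radius = opt$nucleus_radius, spheroid_id = i)
    })
    p1 <- file.path(out_dir, "outgrowths.csv")
    export_results(results, p1, c(n_spheroids = length(results)))
    agg <- aggregate_population(results, opt$axis_deg)
    p2 <- file.path(out_dir, "rose.csv")
    write_csv_commented(agg$rose, p2, c(n_spheroids = length(results)))
    p3 <- file.path(out_dir, "heatmap.csv")
    write.csv(agg$heatmap, p3, row.names = FALSE)
    list(p1, p2, p3)
  } else stop(sprintf("unknown analyze mode '%s'", mode))
}
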