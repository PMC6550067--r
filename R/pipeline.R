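# Configuration, logging and the end-to-end synthetic CLEM experiment.

.myelo_env <- new.env(parent = emptyenv())
.myelo_env$log_level <- "info"

LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set the package log level
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  .myelo_env$log_level <- match.arg(level)
  invisible(.myelo_env$log_level)
}

myelo_log <- function(level, fmt, ...) {
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[.myelo_env$log_level]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Default run configuration
#'
#' One nested list driving the whole synthetic experiment.  Defaults
#' restate the acquisition this package emulates: EM voxels 13.8 x 13.8 nm
#' with 80 nm sections (300 sections per stack), LM voxels
#' 0.068 x 0.068 x 0.3 um (29 sections), axon diameters 1-2 um with
#' g near the 0.6 theoretical optimum, 100 line scans per fibre, and a
#' 6.5 um concentric-ring spacing for the shift analysis.  Tests and
#' examples override `extent_um` / section counts downward to keep
#' runtimes small; the physics (pixel sizes, noise, geometry) is
#' unchanged by that.
#'
#' @param seed integer master seed; every stochastic stage derives its
#'   randomness from it.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(
      fibre = list(d_um = 1.5, D_um = 2.5, length_um = 20),
      label_voxel_um = 0.02,
      margin_um = 0.5,
      node = NULL,                       # or list(gap_length_um=1, n_lamellae=10, ...)
      n_somata = 0L, n_nuclei = 0L,
      soma_axes_um = c(2, 4), nucleus_axes_um = c(1, 2)
    ),
    em = list(voxel_um = c(0.0138, 0.0138, 0.08), n_planes = 300L,
              noise_sd = 12.75, contrast = as.list(default_em_contrast())),
    lm = list(voxel_um = c(0.068, 0.068, 0.3), n_planes = 29L,
              psf = list(modality = "confocal", fwhm_lateral = 0.25,
                         fwhm_axial = 0.6),
              photons = 0, read_noise_sd = 0),
    # tolerance must stay below the axon/background contrast step (50
    # grey levels in the default map) or the grower floods the resin
    segmentation = list(gradient_threshold = 40, intensity_tolerance = 35,
                        max_radius_um = 3, connectivity = "face"),
    morphometry = list(n_scans = 100L, n_samples = 400L, smooth_window = 5L),
    shift = list(ring_spacing_um = 6.5, n_landmarks = 20L,
                 jitter_sd_um = 0.2,
                 transform = list(translation = c(0, 0), scale = c(1, 1),
                                  rotation = 0)),
    outdir = "myelometry_run"
  ), class = "run_config")
}

#' Read / write a run configuration as JSON (lossless round-trip)
#' @param config a `run_config` list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(cfg, class = "run_config")
}

# Merge dotted-key overrides ("em.noise_sd=5") into a config.
apply_overrides <- function(config, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("override must be key=value: '", ov, "'")
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(strsplit(kv[2], ",", fixed = TRUE)[[1]],
                               as.is = TRUE)
    config <- modify_nested(config, keys, val)
  }
  config
}

modify_nested <- function(x, keys, val) {
  if (length(keys) == 1L) { x[[keys]] <- val; return(x) }
  x[[keys[1]]] <- modify_nested(x[[keys[1]]] %||% list(), keys[-1], val)
  x
}

log_paper_defaults <- function(config) {
  myelo_log("info", "EM voxel size %s um (SBF-SEM fine acquisition default)",
            paste(config$em$voxel_um, collapse = " x "))
  myelo_log("info", "LM voxel size %s um (100x Airyscan z-stack default)",
            paste(config$lm$voxel_um, collapse = " x "))
  myelo_log("info", "line scans per fibre: %d", config$morphometry$n_scans)
  myelo_log("info", "shift-analysis ring spacing: %.2f um",
            config$shift$ring_spacing_um)
}

label_grid_for <- function(config) {
  f <- config$phantom$fibre
  vx <- config$phantom$label_voxel_um
  m <- config$phantom$margin_um
  side <- f$D_um + 2 * m
  grid_spec(c(ceiling(side / vx), ceiling(side / vx),
              ceiling((f$length_um + 2 * m) / vx)),
            rep(vx, 3))
}

#' Run the simulation stage
#'
#' Builds the phantom (fibre or node), adds fiducials, renders EM and LM
#' stacks and writes everything (TIFF + ground-truth JSON + fiducial CSV)
#' under `outdir`.
#'
#' @param config a `run_config`.
#' @param outdir output directory (default from the config).
#' @return invisible list of artifact paths and in-memory objects.
#' @export
run_simulate <- function(config, outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_paper_defaults(config)
  set.seed(config$seed)
  grid <- label_grid_for(config)
  f <- config$phantom$fibre
  fs <- straight_fibre(grid, d = f$d_um, D = f$D_um, length = f$length_um)
  nd <- config$phantom$node
  ph <- if (is.null(nd)) build_fibre_phantom(fs, grid)
  else build_node_phantom(fs, node_spec(nd$gap_length_um, nd$n_lamellae,
                                        nd$lamellar_period_um,
                                        nd$paranode_length_um), grid)
  fid <- add_fiducials(ph$labels, config$phantom$n_somata,
                       config$phantom$n_nuclei, seed = config$seed + 1L,
                       soma_axes = unlist(config$phantom$soma_axes_um %||%
                                            c(2, 4)),
                       nucleus_axes = unlist(config$phantom$nucleus_axes_um %||%
                                               c(1, 2)))
  labels <- fid$labels
  truth <- ph$truth
  truth$fiducials <- fid$fiducials

  ext <- grid_extent(grid)
  em_vx <- config$em$voxel_um
  em_grid <- grid_spec(pmax(1, floor(ext / em_vx)), em_vx)
  em <- render_em(labels, em_grid,
                  contrast_map = unlist(config$em$contrast),
                  noise_sd = config$em$noise_sd, seed = config$seed + 2L)
  lm_vx <- config$lm$voxel_um
  lm_grid <- grid_spec(pmax(1, floor(ext / lm_vx)), lm_vx)
  psf <- psf_model(config$lm$psf$modality,
                   fwhm_lateral = config$lm$psf$fwhm_lateral,
                   fwhm_axial = config$lm$psf$fwhm_axial)
  lm <- render_lm(labels, psf, lm_grid, photons = config$lm$photons,
                  read_noise_sd = config$lm$read_noise_sd,
                  seed = config$seed + 3L)

  paths <- list(labels = file.path(outdir, "labels.tif"),
                em = file.path(outdir, "em.tif"),
                lm_myelin = file.path(outdir, "lm_myelin.tif"),
                lm_nuclei = file.path(outdir, "lm_nuclei.tif"),
                truth = file.path(outdir, "ground_truth.json"),
                fiducials = file.path(outdir, "fiducials.csv"))
  write_stack(labels, paths$labels)
  write_stack(em, paths$em, bits = 8L)
  write_stack(lm$myelin, paths$lm_myelin, bits = 32L)
  write_stack(lm$nuclei, paths$lm_nuclei, bits = 32L)
  jsonlite::write_json(list(fibres = truth$fibres,
                            volumes_um3 = as.list(truth$volumes_um3),
                            voxel_counts = as.list(truth$voxel_counts)),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  fidf <- truth$fiducials
  if (nrow(fidf) == 0)
    fidf <- data.frame(axis1_um = numeric(0), axis2_um = numeric(0),
                       axis3_um = numeric(0), material = character(0))
  utils::write.csv(fidf, paths$fiducials, row.names = FALSE)
  myelo_log("info", "simulate: wrote %d artifacts to %s", length(paths), outdir)
  invisible(list(paths = paths, labels = labels, em = em, lm = lm,
                 truth = truth))
}

#' Run segmentation + measurement on a simulated EM stack
#'
#' Seeds the blow segmenter in the myelin (darkest ring) and the axon
#' (center) of the middle section, propagates both through the stack, and
#' writes per-material measurements as CSV.
#'
#' @param config a `run_config`.
#' @param outdir run directory containing `em.tif`.
#' @export
run_segment <- function(config, outdir = config$outdir) {
  em <- read_stack(file.path(outdir, "em.tif"))
  grid <- em$grid
  k0 <- max(2L, grid$shape[3] %/% 2L)
  params <- blow_params(config$segmentation$gradient_threshold,
                        config$segmentation$intensity_tolerance,
                        config$segmentation$max_radius_um,
                        config$segmentation$connectivity)
  ctr_px <- round(grid$shape[1:2] / 2)
  sl <- em$data[, , k0]
  axon_mask <- blow_segment(sl, ctr_px, params,
                            pixel_size = grid$voxel_size[1:2])
  # myelin seed: darkest pixel on the row through the center
  row <- sl[ctr_px[1], ]
  my_seed <- c(ctr_px[1], which.min(row))
  my_mask <- blow_segment(sl, my_seed, params,
                          pixel_size = grid$voxel_size[1:2])
  seg_ax <- propagate_both(em, axon_mask, params, k0, label = 1L)
  seg_my <- propagate_both(em, my_mask, params, k0, label = 2L)
  lab <- seg_ax$data
  lab[seg_my$data == 2L & lab == 0L] <- 2L
  lv <- label_volume(lab, grid)
  write_stack(lv, file.path(outdir, "segmentation.tif"))
  meas <- measure_labels(lv)
  utils::write.csv(meas$summary, file.path(outdir, "measurements.csv"),
                   row.names = FALSE)
  myelo_log("info", "segment: axon %d voxels, myelin %d voxels",
            sum(lab == 1L), sum(lab == 2L))
  invisible(list(labels = lv, measurements = meas))
}

# Propagate from a mid-stack mask towards both ends.
propagate_both <- function(stack, mask, params, k0, label) {
  fwd <- propagate_segmentation(stack, mask, params, start_slice = k0,
                                label = label)
  rev_stack <- image_stack(stack$data[, , rev(seq_len(stack$grid$shape[3])),
                                      drop = FALSE],
                           stack$grid, stack$modality)
  k0r <- stack$grid$shape[3] - k0 + 1L
  bwd <- propagate_segmentation(rev_stack, mask, params, start_slice = k0r,
                                label = label)
  lab <- fwd$data
  back <- bwd$data[, , rev(seq_len(stack$grid$shape[3])), drop = FALSE]
  lab[back == label] <- label
  label_volume(lab, stack$grid)
}

#' Run line-scan morphometry and the three g-ratio estimators
#'
#' @param config a `run_config`.
#' @param outdir run directory containing `em.tif` and
#'   `ground_truth.json`; uses `measurements.csv` (segmentation stage)
#'   for the area/volume estimators when present, otherwise the ground
#'   truth labels.
#' @export
run_gratio <- function(config, outdir = config$outdir) {
  em <- read_stack(file.path(outdir, "em.tif"))
  scans <- scan_fibre_diameters(
    em, n_scans = config$morphometry$n_scans,
    n_samples = config$morphometry$n_samples,
    smooth_window = config$morphometry$smooth_window)
  utils::write.csv(
    cbind(fibre_id = 1L, scans,
          orientation = "orthogonal", modality = "em",
          g = scans$d_um / scans$D_um),
    file.path(outdir, "line_scans.csv"), row.names = FALSE)
  g_d <- g_ratio_diameter(scans)

  segf <- file.path(outdir, "segmentation.tif")
  lv <- read_stack(if (file.exists(segf)) segf
                   else file.path(outdir, "labels.tif"))
  sa <- measure_labels(lv)$slice_areas_um2
  # restrict both compartments to the sections where both were
  # segmented, so area and volume ratios compare like with like
  ok <- sa["axon", ] > 0 & sa["myelin", ] > 0
  if (!any(ok)) stop("no sections with both axon and myelin labels")
  g_a <- g_ratio_area(sa["axon", ok], sa["axon", ok] + sa["myelin", ok])
  dz <- lv$grid$voxel_size[3]
  g_v <- g_ratio_volume(sum(sa["axon", ok]) * dz,
                        sum(sa["axon", ok] + sa["myelin", ok]) * dz)
  summary <- list(
    convention = "area and volume g-ratios are sqrt(ratio), commensurate with d/D",
    n_failed_scans = attr(scans, "n_failed"),
    diameter = g_summary(g_d), area = g_summary(g_a), volume = g_summary(g_v))
  jsonlite::write_json(summary, file.path(outdir, "gratio_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  myelo_log("info", "gratio: diameter %.3f, area %.3f, volume %.3f",
            g_d$mean, g_a$mean, g_v$mean)
  invisible(list(diameter = g_d, area = g_a, volume = g_v, scans = scans))
}

g_summary <- function(g) list(method = g$method, n = g$n, mean = g$mean,
                              sd = g$sd, sem = g$sem)

#' Run the landmark shift analysis stage
#'
#' Draws landmark positions around the stack center, maps them to the
#' "EM" frame through the configured modality transform plus isotropic
#' jitter, computes per-landmark shifts and writes CSV + JSON summaries.
#'
#' @param config a `run_config`.
#' @param outdir run directory.
#' @export
run_shift <- function(config, outdir = config$outdir) {
  sc <- config$shift
  set.seed(config$seed + 4L)
  n <- sc$n_landmarks
  pts <- matrix(stats::runif(2 * n, -20, 20), ncol = 2)
  pts[1, ] <- c(0, 0)                       # origin landmark
  tr <- modality_transform(sc$transform$translation, sc$transform$scale,
                           sc$transform$rotation)
  em <- apply_modality_transform(pts, tr) +
    matrix(stats::rnorm(2 * n, sd = sc$jitter_sd_um), ncol = 2)
  cs <- correspondence_set(pts, em, origin_index = 1L,
                           class = rep(c("myelin", "nucleus"), length.out = n))
  write_correspondences(cs, file.path(outdir, "correspondences.csv"))
  res <- compute_shifts(cs, ring_spacing = sc$ring_spacing_um)
  trend <- shift_trend(res)
  utils::write.csv(res$table, file.path(outdir, "shifts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n = res$n, mean_shift_um = res$mean_shift_um,
         sd_shift_um = res$sd_shift_um, verdict = trend$verdict,
         trend = trend[c("vs_r", "vs_angle")],
         distance_convention = "r measured at the mean of the centred LM/EM positions"),
    file.path(outdir, "shift_summary.json"), auto_unbox = TRUE, digits = NA)
  myelo_log("info", "shift: mean %.3f um (+/- %.3f), verdict %s",
            res$mean_shift_um, res$sd_shift_um, trend$verdict)
  invisible(list(result = res, trend = trend))
}

#' Write the run report
#'
#' Collects the stage summaries plus provenance (config, seed, package
#' version) into `report.json`; byte-identical across reruns of the same
#' config and seed.
#'
#' @param config a `run_config`.
#' @param outdir run directory.
#' @export
run_report <- function(config, outdir = config$outdir) {
  read_if <- function(p) if (file.exists(p)) jsonlite::fromJSON(p) else NULL
  truth <- read_if(file.path(outdir, "ground_truth.json"))
  gr <- read_if(file.path(outdir, "gratio_summary.json"))
  checks <- list()
  if (!is.null(truth) && !is.null(gr)) {
    g_true <- truth$fibres$g[1]
    checks$volume_g_within_0.02 <- abs(gr$volume$mean - g_true) <= 0.02
  }
  report <- list(package_version = as.character(utils::packageVersion("myelometry")),
                 seed = config$seed, config = unclass(config),
                 ground_truth = truth, gratio = gr,
                 shift = read_if(file.path(outdir, "shift_summary.json")),
                 checks = checks)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}

#' Run the full synthetic experiment
#' @param config a `run_config`.
#' @param outdir run directory.
#' @export
run_all <- function(config, outdir = config$outdir) {
  run_simulate(config, outdir)
  run_segment(config, outdir)
  run_gratio(config, outdir)
  run_shift(config, outdir)
  run_report(config, outdir)
}

#' Command-line entry point
#'
#' `myelo_cli(c("simulate", "--config", "cfg.json", "--seed", "7",
#' "--outdir", "out", "em.noise_sd=5"))`.  Subcommands: simulate,
#' segment, reslice, measure, gratio, shift, report, all.  Positional
#' `key=value` arguments override nested config entries via dotted keys.
#'
#' @param args character vector (default `commandArgs(TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
myelo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: myelometry <simulate|segment|reslice|measure|gratio|shift|report|all> ",
            "[--config cfg.json] [--seed N] [--outdir DIR] [--log-level L] [key=value ...]")
    return(invisible(1L))
  }
  sub <- args[1]
  valid <- c("simulate", "segment", "reslice", "measure", "gratio",
             "shift", "report", "all")
  if (!sub %in% valid)
    stop("unknown subcommand '", sub, "'; expected one of: ",
         paste(valid, collapse = ", "))
  rest <- args[-1]
  opt <- list(config = NULL, seed = NULL, outdir = NULL, log_level = NULL)
  overrides <- character(0)
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (a %in% c("--config", "--seed", "--outdir", "--log-level")) {
      if (i == length(rest)) stop("missing value for ", a)
      key <- sub("^--", "", a); key <- gsub("-", "_", key)
      opt[[key]] <- rest[i + 1L]
      i <- i + 2L
    } else if (grepl("=", a, fixed = TRUE)) {
      overrides <- c(overrides, a)
      i <- i + 1L
    } else stop("unrecognized argument: ", a)
  }
  if (!is.null(opt$log_level)) set_log_level(opt$log_level)
  config <- if (!is.null(opt$config)) read_config(opt$config)
  else default_config()
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) config$outdir <- opt$outdir
  if (length(overrides)) config <- apply_overrides(config, overrides)
  bad <- validate_config(config)
  if (length(bad))
    stop("invalid config; offending keys: ", paste(bad, collapse = ", "))
  switch(sub,
         simulate = run_simulate(config),
         segment = run_segment(config),
         reslice = run_reslice(config),
         measure = run_measure(config),
         gratio = run_gratio(config),
         shift = run_shift(config),
         report = run_report(config),
         all = run_all(config))
  invisible(0L)
}

#' Validate a run configuration
#' @param config a `run_config`.
#' @return character vector of offending keys (empty when valid).
#' @export
validate_config <- function(config) {
  bad <- character(0)
  chk <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed")
  f <- config$phantom$fibre
  chk(is.numeric(f$d_um) && f$d_um > 0, "phantom.fibre.d_um")
  chk(is.numeric(f$D_um) && f$D_um > f$d_um, "phantom.fibre.D_um")
  chk(is.numeric(f$length_um) && f$length_um > 0, "phantom.fibre.length_um")
  chk(config$phantom$label_voxel_um > 0, "phantom.label_voxel_um")
  chk(all(unlist(config$em$voxel_um) > 0), "em.voxel_um")
  chk(all(unlist(config$lm$voxel_um) > 0), "lm.voxel_um")
  chk(config$morphometry$n_scans >= 1, "morphometry.n_scans")
  chk(config$shift$ring_spacing_um > 0, "shift.ring_spacing_um")
  bad
}

#' Re-section a simulated stack (reslice stage)
#'
#' Writes the middle orthogonal cross-section of the EM stack plus
#' thickness-matched mean projections of the EM and LM stacks.
#'
#' @param config a `run_config`.
#' @param outdir run directory.
#' @export
run_reslice <- function(config, outdir = config$outdir) {
  em <- read_stack(file.path(outdir, "em.tif"))
  grid <- em$grid
  ext <- grid_extent(grid)
  ctr <- grid$origin + ext / 2
  pl <- plane_spec(ctr, normal = c(0, 0, 1), up = c(1, 0, 0),
                   pixel_size = grid$voxel_size[1],
                   extent = ext[1:2] * 0.9)
  xs <- multiplanar_reslice(em, pl)
  write_tiff(matrix(as.numeric(xs), nrow(xs)),
             file.path(outdir, "cross_section.tif"),
             voxel_size = c(attr(xs, "pixel_size"), attr(xs, "pixel_size"), 1))
  t_lm <- config$lm$voxel_um[[3]] * min(9L, grid$shape[3])
  mp <- match_projection_thickness(t_lm, grid$voxel_size[3])
  n_em <- min(mp$n, grid$shape[3])
  pr <- project(em, projection_spec(1L, n_em, grid$voxel_size[3]))
  write_tiff(pr$image, file.path(outdir, "em_projection.tif"),
             voxel_size = c(grid$voxel_size[1:2], pr$thickness_um))
  jsonlite::write_json(list(reference_thickness_um = t_lm,
                            n_sections = n_em,
                            achieved_um = pr$thickness_um),
                       file.path(outdir, "projection.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cross_section = xs, projection = pr))
}

#' Measure the ground-truth labels (measure stage)
#' @param config a `run_config`.
#' @param outdir run directory containing `labels.tif` or
#'   `segmentation.tif`.
#' @export
run_measure <- function(config, outdir = config$outdir) {
  p <- file.path(outdir, "segmentation.tif")
  if (!file.exists(p)) p <- file.path(outdir, "labels.tif")
  lv <- read_stack(p)
  meas <- measure_labels(lv)
  utils::write.csv(meas$summary, file.path(outdir, "measurements.csv"),
                   row.names = FALSE)
  invisible(meas)
}
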