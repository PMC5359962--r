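# End-to-end orchestration: configuration, the full pipeline, reporting.

#' Default pipeline configuration
#'
#' Returns the full configuration tree with defaults; any entry can be
#' overridden by the arguments (named lists are merged one level deep). The
#' same structure round-trips through a YAML file (see [read_config()]).
#'
#' @param ... Named overrides, e.g. `cell = list(extension_px = 8)`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL,           # path to a TIFF stack (or supply `stack` to run_pipeline)
    out_dir = NULL,
    geometry = list(pixel_size_x_nm = 6.3, pixel_size_y_nm = 6.3,
                    slice_thickness_nm = 40, view_angle_deg = 0),
    seed = 1L,
    drift = list(enabled = TRUE, subpixel = FALSE),
    view_angle = list(convention = "cos"),
    wiener = list(window = 5),
    lowpass = list(sigma = 1.5),
    cell = list(threshold = "otsu", extension_px = 10, smooth_radius_px = 5,
                notch_tolerance = 0.1, contrast_min = 0.05),
    np = list(roberts_k = 3, margin_xy = 5, margin_z = 3, min_voxels = 4),
    calibration = list(file = NULL, singles = NULL, noise_floor = 3,
                       estimator = "empirical", diameter_nm = 74,
                       area_tolerance = 0.3),
    report = list(bin_width = 10, export_meshes = TRUE, histogram = TRUE)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] structure.
#' @return A `pipeline_config` (missing keys filled with defaults).
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  voxel_geometry(g$pixel_size_x_nm, g$pixel_size_y_nm, g$slice_thickness_nm,
                 g$view_angle_deg)
}

#' Run the full quantification pipeline
#'
#' Executes preprocessing (drift registration, view-angle correction), cell
#' segmentation, NP detection, single-particle calibration and cluster
#' quantification, and writes the run artifacts (cluster CSV, calibration
#' and dose JSON, size-distribution figure, surface meshes, log) into
#' `config$out_dir` when set. Every stage logs its parameters and counts.
#' The run is deterministic given the configuration and input.
#'
#' @param config A [pipeline_config()].
#' @param stack Optionally, an [image_stack()] already in memory; otherwise
#'   `config$input` is read via [read_stack()].
#' @return An object of class `fib_pipeline`: `dose` (a `dose_report`),
#'   `calibration`, `clusters`, `cell` (segmentation summary), `drift`
#'   (trace or NULL), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), stack = NULL) {
  logfile <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(config$out_dir, "run.log")
    if (file.exists(logfile)) file.remove(logfile)
  }
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[fibcount] ", msg)
    if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (is.null(stack)) {
    if (is.null(config$input)) stop("no input: set config$input or pass `stack`")
    stack <- stage("read", read_stack(config$input, config_geometry(config)))
  }
  d <- dim(stack)
  say("input stack: %d x %d px, %d slices", d[1], d[2], d[3])

  drift_trace <- NULL
  if (isTRUE(config$drift$enabled) && d[3] >= 2) {
    drift_trace <- stage("drift", estimate_drift(stack,
                                                 subpixel = isTRUE(config$drift$subpixel)))
    stack <- stage("drift", apply_drift_correction(stack, drift_trace))
    say("drift: max |shift| %d px", max(abs(drift_trace)))
  }
  if (stack$geometry$view_angle > 0 && config$view_angle$convention != "none") {
    stack <- stage("view_angle",
                   correct_view_angle(stack, config$view_angle$convention))
    say("view-angle correction applied (%s convention)", config$view_angle$convention)
  }

  fixed_thr <- NULL
  if (is.character(config$cell$threshold) &&
      grepl("^fixed:", config$cell$threshold)) {
    fixed_thr <- as.numeric(sub("^fixed:", "", config$cell$threshold))
  }
  cellseg <- stage("cell", segment_cell_stack(
    stack, wiener_window = config$wiener$window,
    extension_px = config$cell$extension_px,
    smooth_radius_px = config$cell$smooth_radius_px,
    notch_tolerance = config$cell$notch_tolerance,
    contrast_min = config$cell$contrast_min,
    threshold = fixed_thr))
  say("cell segmentation: %.0f%% of slices below contrast limit",
      100 * cellseg$flagged_fraction)

  geom <- stack$geometry
  aiu <- array(0, d <- dim(stack))
  for (k in seq_len(d[3])) {
    m <- cellseg$masks[[k]]$mask
    if (!any(m)) next
    aiu[, , k] <- stage("aiu", normalize_to_background(
      stack$slices[[k]], m,
      bg_erode_px = config$cell$extension_px + config$cell$smooth_radius_px))
  }

  clusters <- stage("np_detection", detect_np_clusters(
    aiu, cellseg$volume,
    lowpass_sigma = config$lowpass$sigma, roberts_k = config$np$roberts_k,
    margin_xy = config$np$margin_xy, margin_z = config$np$margin_z,
    min_voxels = config$np$min_voxels))
  say("NP detection: %d clusters", length(clusters))

  cal <- NULL
  if (!is.null(config$calibration$file)) {
    cal <- stage("calibration", read_calibration(config$calibration$file))
    say("calibration loaded from %s", config$calibration$file)
  } else if (length(clusters) > 0) {
    A_expected <- pi * (config$calibration$diameter_nm / 2 / geom$pixel_size_x)^2
    singles <- stage("calibration", select_single_nps(
      clusters, aiu, A_expected,
      tolerance = config$calibration$area_tolerance,
      diameter_nm = config$calibration$diameter_nm,
      slice_thickness = geom$slice_thickness,
      noise_floor = config$calibration$noise_floor,
      manual = config$calibration$singles))
    if (length(singles) == 0) {
      stop("pipeline stage 'calibration' failed: no single particles found; ",
           "supply config$calibration$file or a manual singles list", call. = FALSE)
    }
    say("calibration: %d reference singles", length(singles))
    cal <- stage("calibration", calibrate(
      aiu, singles, geom, noise_floor = config$calibration$noise_floor,
      estimator = config$calibration$estimator))
    say("calibration: l = %.3g nm, Vs0 = %.4g a.i.u., As = %.4g px",
        cal$l_nm, cal$Vs0, cal$As_px)
  }

  dose <- stage("quantify", total_dose(clusters, cal,
                                       bin_width = config$report$bin_width))
  say("dose: %d +- %.0f particles in %d clusters", dose$N, dose$N_sd,
      nrow(dose$clusters))

  result <- structure(list(dose = dose, calibration = cal, clusters = clusters,
                           cell = list(flagged_fraction = cellseg$flagged_fraction,
                                       volume_voxels = sum(cellseg$volume)),
                           drift = drift_trace, config = config),
                      class = "fib_pipeline")

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    write.csv(dose$clusters, file.path(out, "clusters.csv"), row.names = FALSE)
    if (!is.null(cal)) write_calibration(cal, file.path(out, "calibration.json"))
    dist <- dose$distribution
    jsonlite::write_json(list(
      N = dose$N, N_sd = dose$N_sd, N_fractional = dose$N_fractional,
      n_clusters = nrow(dose$clusters),
      fraction_1_5 = dist$fraction_1_5,
      fraction_ge_20 = dist$fraction_ge_20,
      histogram = dist$histogram, cdf = dist$cdf,
      cell_flagged_fraction = cellseg$flagged_fraction
    ), file.path(out, "dose.json"), auto_unbox = TRUE, digits = 10, na = "null")
    if (isTRUE(config$report$histogram) && !dist$empty) {
      try({
        grDevices::png(file.path(out, "size_distribution.png"), 800, 500)
        plot(dose)
        grDevices::dev.off()
      }, silent = TRUE)
    }
    if (isTRUE(config$report$export_meshes)) {
      try({
        if (any(cellseg$volume)) {
          export_surface_mesh(cellseg$volume * 1L, geom,
                              file.path(out, "cell.stl"))
        }
        if (length(clusters) > 0) {
          labs <- array(0L, d)
          for (cl in clusters) labs[cl$voxels] <- 1L
          export_surface_mesh(labs, geom, file.path(out, "np.stl"))
        }
      }, silent = TRUE)
    }
    say("artifacts written to %s", out)
  }
  result
}

#' @export
print.fib_pipeline <- function(x, ...) {
  cat("FIB/SEM quantification run\n")
  if (!is.null(x$drift)) {
    cat(sprintf("  drift-corrected, max |shift| %d px\n", max(abs(x$drift))))
  }
  cat(sprintf("  cell: %.0f%% of slices below contrast limit\n",
              100 * x$cell$flagged_fraction))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: n_ref = %d, l = %.3g nm\n",
                x$calibration$n_ref, x$calibration$l_nm))
  }
  print(x$dose)
  invisible(x)
}
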