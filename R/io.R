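# Plain-text scan archive, display-window export, and run configuration.
#
# A scan archive is a directory holding meta.json (acquisition settings,
# layout, ground truth, rescale slope/intercept, per-slice records with z
# positions) and one whitespace-separated text matrix per slice. Stored
# values are converted to HU on read via HU = slope * stored + intercept,
# the usual CT rescale convention, so archives written by other tools with
# integer stored values round-trip correctly.

#' Write a simulated scan to a plain-text archive
#'
#' @param scan A `ddc_scan`.
#' @param dir Target directory (created if needed).
#' @param rescale_slope,rescale_intercept Stored-value rescale; stored =
#'   (HU - intercept) / slope.
#' @return The directory, invisibly.
#' @export
write_scan <- function(scan, dir, rescale_slope = 1, rescale_intercept = 0) {
  stopifnot(inherits(scan, "ddc_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(scan$volume)
  slice_files <- sprintf("slice_%03d.txt", seq_len(d[3]))
  zs <- (seq_len(d[3]) - 1) * scan$settings$slice_thickness_mm
  for (s in seq_len(d[3])) {
    stored <- (scan$volume[, , s] - rescale_intercept) / rescale_slope
    write.table(format(stored, digits = 17, trim = TRUE, scientific = FALSE),
                file.path(dir, slice_files[s]),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  write.table(scan$truth$rod_label, file.path(dir, "rod_label.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(1L * scan$truth$background, file.path(dir, "background.txt"),
              row.names = FALSE, col.names = FALSE)
  st <- unclass(scan$settings)
  st$scan_date <- format(st$scan_date)
  st$kv_response <- as.list(st$kv_response)  # keep names in JSON
  meta <- list(dims = d,
               rescale_slope = rescale_slope,
               rescale_intercept = rescale_intercept,
               slices = data.frame(file = slice_files, z_mm = zs),
               settings = st, layout = unclass(scan$layout),
               transform = scan$transform,
               truth_rods = scan$truth$rods,
               base_hu = scan$base_hu, body_hu = scan$body_hu,
               noise_sigma_hu = scan$noise_sigma_hu, seed = scan$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scan archive
#'
#' Slices are sorted by their recorded z position regardless of file order,
#' and stored values are rescaled to HU.
#'
#' @param dir Archive directory.
#' @return A `ddc_scan`.
#' @export
read_scan <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop_ddcqa("%s is not a scan archive (no meta.json)", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$rescale_slope) || is.null(meta$rescale_intercept))
    stop_ddcqa("archive %s lacks rescale slope/intercept", dir)
  d <- unlist(meta$dims)
  sl <- as.data.frame(meta$slices)
  sl <- sl[order(sl$z_mm), , drop = FALSE]
  vol <- array(NA_real_, dim = d)
  for (s in seq_len(nrow(sl))) {
    m <- as.matrix(read.table(file.path(dir, sl$file[s])))
    vol[, , s] <- meta$rescale_slope * m + meta$rescale_intercept
  }
  st <- meta$settings
  settings <- acquisition_settings(kv = st$kv, ctdi_vol_mgy = st$ctdi_vol_mgy,
                                   pixel_spacing_mm = st$pixel_spacing_mm,
                                   slice_thickness_mm = st$slice_thickness_mm,
                                   n_slices = st$n_slices,
                                   psf_fwhm_mm = st$psf_fwhm_mm,
                                   noise_sigma_ref_hu = st$noise_sigma_ref_hu,
                                   ctdi_ref_mgy = st$ctdi_ref_mgy,
                                   kernel_label = st$kernel_label,
                                   scan_date = as.Date(st$scan_date),
                                   kv_response = unlist(st$kv_response))
  layout <- structure(meta$layout, class = "ddc_layout")
  layout$rods <- as.data.frame(layout$rods)
  truth <- NULL
  if (file.exists(file.path(dir, "rod_label.txt")))
    truth <- list(rod_label = as.matrix(read.table(file.path(dir, "rod_label.txt"))),
                  background = as.matrix(read.table(file.path(dir, "background.txt"))) > 0,
                  rods = as.data.frame(meta$truth_rods))
  if (!is.null(truth)) dimnames(truth$rod_label) <- dimnames(truth$background) <- NULL
  structure(list(volume = vol, settings = settings, layout = layout,
                 transform = meta$transform, truth = truth,
                 base_hu = meta$base_hu, body_hu = meta$body_hu,
                 noise_sigma_hu = meta$noise_sigma_hu, seed = meta$seed),
            class = "ddc_scan")
}

#' Map HU values to 8-bit display values through a window
#'
#' Linear mapping of `[wc - ww/2, wc + ww/2]` to `[0, 255]` with clipping
#' and round-half-up, the display convention used during observer sessions
#' (abdomen window ww 400 / wc 60).
#'
#' @param hu Numeric matrix (or vector) of HU values.
#' @param ww Window width, HU; must be positive.
#' @param wc Window centre, HU.
#' @return Integer values in 0..255, same shape as `hu`.
#' @export
window_display <- function(hu, ww = 400, wc = 60) {
  if (ww <= 0) stop_ddcqa("window width must be positive")
  v <- (hu - (wc - ww / 2)) / ww * 255
  v <- pmin(pmax(v, 0), 255)
  out <- floor(v + 0.5)  # round half up
  storage.mode(out) <- "integer"
  out
}

#' Export a windowed slice as a PNG image
#'
#' @param x A `ddc_scan` (central slice is exported) or an HU matrix.
#' @param path Output PNG path.
#' @param ww,wc Display window (see [window_display()]).
#' @param slice Slice index when `x` is a scan.
#' @return The 8-bit matrix, invisibly.
#' @export
export_display <- function(x, path, ww = 400, wc = 60, slice = NULL) {
  mat <- if (inherits(x, "ddc_scan")) {
    if (is.null(slice)) slice <- ceiling(dim(x$volume)[3] / 2)
    x$volume[, , slice]
  } else x
  v8 <- window_display(mat, ww, wc)
  png::writePNG(v8 / 255, path)
  invisible(v8)
}

#' Read a pipeline run configuration
#'
#' Flat YAML key-value configuration for the CLI; unknown keys are
#' rejected, numeric options are validated against the same preconditions
#' as the corresponding functions.
#'
#' @param path YAML file.
#' @return Named list of class `ddc_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "layout_seed", "module_type", "min_gap_mm", "edge_margin_mm",
             "kv", "ctdi_vol_mgy", "pixel_spacing_mm", "slice_thickness_mm",
             "n_slices", "psf_fwhm_mm", "noise_sigma_ref_hu", "ctdi_ref_mgy",
             "kernel_label", "rotation_deg", "base_hu", "body_hu",
             "erode_px", "threshold", "width", "false_click_rate",
             "tolerance_mm", "k", "m", "observer_bias", "ww", "wc")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_ddcqa("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  num_pos <- c("ctdi_vol_mgy", "pixel_spacing_mm", "slice_thickness_mm",
               "n_slices", "ctdi_ref_mgy", "width", "ww", "m")
  for (nm in intersect(num_pos, names(cfg)))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop_ddcqa("configuration key '%s' must be a positive number", nm)
  if (!is.null(cfg$module_type) &&
      !cfg$module_type %in% c("native", "contrast_agent"))
    stop_ddcqa("module_type must be 'native' or 'contrast_agent'")
  structure(cfg, class = "ddc_config")
}
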