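# Automated ROI extraction and contrast verification.

# Integer (row, col) offsets of a disc structuring element: all offsets
# whose centre lies within radius diameter/2 of the origin.
disc_offsets <- function(disc_diameter_px) {
  r <- disc_diameter_px / 2
  f <- floor(r)
  g <- expand.grid(dr = -f:f, dc = -f:f)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

shift_mask <- function(mask, dr, dc, fill = FALSE) {
  out <- matrix(fill, nrow(mask), ncol(mask))
  rs <- seq_len(nrow(mask)) - dr
  cs <- seq_len(ncol(mask)) - dc
  ok_r <- rs >= 1 & rs <= nrow(mask)
  ok_c <- cs >= 1 & cs <= ncol(mask)
  out[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

#' Morphological erosion and dilation of a pixel mask
#'
#' Erodes (or dilates) a logical mask by a disc structuring element that
#' contains every integer offset whose centre lies within radius
#' `disc_diameter_px / 2`. Eroding ROI masks discards their periphery so
#' that template-positioning inaccuracies and partial-volume edge pixels do
#' not contaminate the statistics. An empty erosion result is legal and is
#' flagged downstream, never an error.
#'
#' @param mask Logical matrix.
#' @param disc_diameter_px Disc diameter in pixels (default 5).
#' @return Logical matrix of the same shape.
#' @export
erode_roi <- function(mask, disc_diameter_px = 5) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop_ddcqa("cannot erode an empty mask")
  off <- disc_offsets(disc_diameter_px)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(mask, -off$dr[i], -off$dc[i], fill = FALSE)
  out
}

#' @rdname erode_roi
#' @export
dilate_roi <- function(mask, disc_diameter_px = 5) {
  stopifnot(is.matrix(mask))
  off <- disc_offsets(disc_diameter_px)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dr[i], off$dc[i], fill = FALSE)
  out
}

# Rod and background masks in image space from a layout and a transform
# (pixel-centre-in-footprint rule). The background is the barrel interior
# minus the rim margin and minus all rod footprints dilated by 2 mm.
layout_masks <- function(layout, transform, nrow_img, ncol_img) {
  rows <- seq_len(nrow_img); cols <- seq_len(ncol_img)
  pm <- px_to_module(transform, rep(rows, times = ncol_img), rep(cols, each = nrow_img))
  rods <- layout$rods
  label <- matrix(0L, nrow_img, ncol_img)
  near_rod <- matrix(FALSE, nrow_img, ncol_img)
  for (i in seq_len(nrow(rods))) {
    d2 <- (pm$x_mm - rods$x_mm[i])^2 + (pm$y_mm - rods$y_mm[i])^2
    label[d2 <= (rods$diameter_mm[i] / 2)^2] <- rods$rod_id[i]
    near_rod <- near_rod | d2 <= (rods$diameter_mm[i] / 2 + 2)^2
  }
  inside <- matrix(pm$x_mm^2 + pm$y_mm^2 <=
                     (layout$barrel_diameter_mm / 2 - layout$edge_margin_mm)^2,
                   nrow_img, ncol_img)
  list(rod_label = label, background = inside & !near_rod)
}

#' Eroded ROI masks for a scan geometry
#'
#' Builds the rod and background masks for a layout under a module-to-pixel
#' transform and erodes each by the disc element. Useful to precompute when
#' many volumes share one geometry (e.g. noise replicates).
#'
#' @param layout A [ddc_layout()].
#' @param transform Module-to-pixel transform.
#' @param dim_px Length-2 image dimension (rows, cols).
#' @param disc_diameter_px Erosion disc diameter, px.
#' @return List with `rod` (per-rod logical matrices, in `layout$rods`
#'   order) and `background`.
#' @export
roi_masks <- function(layout, transform, dim_px, disc_diameter_px = 5) {
  mk <- layout_masks(layout, transform, dim_px[1], dim_px[2])
  rod <- lapply(layout$rods$rod_id, function(id) {
    m <- mk$rod_label == id
    if (!any(m)) m else erode_roi(m, disc_diameter_px)
  })
  list(rod = stats::setNames(rod, sprintf("rod%02d", layout$rods$rod_id)),
       background = erode_roi(mk$background, disc_diameter_px))
}

agg_stats <- function(v) {
  if (!length(v))
    return(c(n_px = 0, mean = NA, sd = NA, min = NA, max = NA, median = NA))
  c(n_px = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
    min = min(v), max = max(v), median = median(v))
}

#' Per-rod and background ROI statistics of a scan
#'
#' Builds rod and background masks from the module layout and the (true or
#' registered) module-to-pixel transform, erodes each by the disc element,
#' selects the central slices, and computes mean / sd / min / max / median
#' HU per ROI, per slice and aggregated across the selected slices. The
#' measured contrast of a rod is its aggregate mean minus the background
#' aggregate mean. A rod whose eroded mask is empty is flagged
#' `unmeasurable` (statistics `NA`), not an error.
#'
#' @param scan A `ddc_scan` (or any list with `volume`, `layout`,
#'   `settings`, `transform`).
#' @param transform Module-to-pixel transform; default is the scan's own
#'   (ground-truth) transform. Pass the result of [register_template()] for
#'   the registration-based pipeline.
#' @param slices Slice indices to evaluate; by default the first and last
#'   slice are dropped (module face effects), keeping at least one.
#' @param disc_diameter_px Erosion disc diameter, px.
#' @param masks Optional precomputed [roi_masks()] for this geometry.
#' @return Object of class `ddc_roi_stats`: `rods` (aggregate per-rod table
#'   with measured and, when available, rendered contrast), `background`
#'   (aggregate background row), `per_slice`, and the acquisition metadata.
#' @export
rod_statistics <- function(scan, transform = NULL, slices = NULL,
                           disc_diameter_px = 5, masks = NULL) {
  vol <- scan$volume
  if (is.null(transform)) transform <- scan$transform
  nsl <- dim(vol)[3]
  if (is.null(slices))
    slices <- if (nsl >= 3) 2:(nsl - 1) else seq_len(nsl)
  if (!length(slices) || any(slices < 1 | slices > nsl))
    stop_ddcqa("invalid slice selection")
  if (is.null(masks))
    masks <- roi_masks(scan$layout, transform, dim(vol)[1:2], disc_diameter_px)
  rods <- scan$layout$rods
  per_slice <- list(); agg <- list()
  rois <- c(masks$rod, list(background = masks$background))
  for (nm in names(rois)) {
    idx <- which(rois[[nm]])
    vals_all <- numeric(0)
    for (s in slices) {
      sl <- vol[, , s]
      v <- sl[idx]
      per_slice[[length(per_slice) + 1L]] <-
        data.frame(roi = nm, slice = s, t(agg_stats(v)))
      vals_all <- c(vals_all, v)
    }
    agg[[nm]] <- agg_stats(vals_all)
  }
  aggm <- do.call(rbind, agg)
  bg_mean <- aggm["background", "mean"]
  rod_tab <- data.frame(rods[, c("rod_id", "diameter_mm", "contrast_hu")],
                        as.data.frame(aggm[seq_len(nrow(rods)), , drop = FALSE]))
  names(rod_tab)[names(rod_tab) == "contrast_hu"] <- "target_contrast_hu"
  rod_tab$measured_contrast_hu <- rod_tab$mean - bg_mean
  rod_tab$unmeasurable <- rod_tab$n_px == 0
  if (!is.null(scan$truth))
    rod_tab$rendered_contrast_hu <-
      scan$truth$rods$rendered_contrast_hu[match(rod_tab$rod_id, scan$truth$rods$rod_id)]
  rownames(rod_tab) <- NULL
  st <- scan$settings
  structure(list(rods = rod_tab,
                 background = data.frame(t(agg[["background"]])),
                 per_slice = do.call(rbind, per_slice), slices = slices,
                 disc_diameter_px = disc_diameter_px,
                 kv = st$kv, ctdi_vol_mgy = st$ctdi_vol_mgy,
                 scan_date = st$scan_date, kernel_label = st$kernel_label,
                 module_type = scan$layout$module_type),
            class = "ddc_roi_stats")
}

#' @export
print.ddc_roi_stats <- function(x, ...) {
  cat(sprintf("ROI statistics: %d rods, background mean %.1f HU (%d px), slices %s\n",
              nrow(x$rods), x$background$mean, x$background$n_px,
              paste(x$slices, collapse = ",")))
  if (any(x$rods$unmeasurable))
    cat(sprintf("  %d rod(s) unmeasurable after erosion\n", sum(x$rods$unmeasurable)))
  invisible(x)
}

#' Contrast measurements table from ROI statistics
#'
#' Flattens one or more [rod_statistics()] results into the long
#' measurement format used by the verification analyses
#' ([fit_linearity()], [energy_response()], [drift_summary()]).
#'
#' @param ... `ddc_roi_stats` objects (or a single list of them).
#' @return Data frame with one row per measurable rod and columns
#'   `diameter_mm`, `target_contrast_hu`, `measured_contrast_hu`,
#'   `module_type`, `kv`, `ctdi_vol_mgy`, `scan_date`, `kernel_label`.
#' @export
contrast_measurements <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "ddc_roi_stats")) xs <- xs[[1]]
  do.call(rbind, lapply(xs, function(s) {
    stopifnot(inherits(s, "ddc_roi_stats"))
    r <- s$rods[!s$rods$unmeasurable, ]
    data.frame(diameter_mm = r$diameter_mm,
               target_contrast_hu = r$target_contrast_hu,
               measured_contrast_hu = r$measured_contrast_hu,
               module_type = s$module_type, kv = s$kv,
               ctdi_vol_mgy = s$ctdi_vol_mgy,
               scan_date = as.Date(s$scan_date), kernel_label = s$kernel_label,
               stringsAsFactors = FALSE)
  }))
}

#' Per-diameter linearity of measured versus target contrast
#'
#' Regresses measured on target contrast separately for each rod diameter.
#' A perfectly manufactured and reconstructed module would give slope 1,
#' intercept 0 for every diameter.
#'
#' @param measurements Data frame with `diameter_mm`, `target_contrast_hu`,
#'   `measured_contrast_hu` (see [contrast_measurements()]).
#' @return Data frame with `diameter_mm`, `slope`, `intercept_hu`,
#'   `r_squared`, `n`.
#' @export
fit_linearity <- function(measurements) {
  out <- lapply(split(measurements, measurements$diameter_mm), function(g) {
    if (length(unique(g$target_contrast_hu)) < 2)
      stop_ddcqa("diameter %g mm has < 2 distinct target contrasts; linearity is not estimable",
                 g$diameter_mm[1])
    f <- lm(measured_contrast_hu ~ target_contrast_hu, data = g)
    sst <- sum((g$measured_contrast_hu - mean(g$measured_contrast_hu))^2)
    data.frame(diameter_mm = g$diameter_mm[1],
               slope = unname(coef(f)[2]), intercept_hu = unname(coef(f)[1]),
               r_squared = if (sst > 0) 1 - sum(residuals(f)^2) / sst else NA_real_,
               n = nrow(g))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Energy (tube-voltage) response of the measured contrasts
#'
#' Regresses measured on target contrast per (module type, tube voltage).
#' Native (sucrose) rods have the same slope at every voltage; NaI rods'
#' slopes follow the kV contrast response of iodine.
#'
#' @param measurements See [contrast_measurements()]; must span at least
#'   two voltages.
#' @return Data frame with `module_type`, `kv`, `slope`, `intercept_hu`,
#'   `n`, plus `slope_ratio_vs_120kv` where a 120 kV group is present.
#' @export
energy_response <- function(measurements) {
  if (length(unique(measurements$kv)) < 2)
    stop_ddcqa("energy response needs measurements at >= 2 tube voltages")
  out <- lapply(split(measurements,
                      list(measurements$module_type, measurements$kv), drop = TRUE),
                function(g) {
                  f <- lm(measured_contrast_hu ~ target_contrast_hu, data = g)
                  data.frame(module_type = g$module_type[1], kv = g$kv[1],
                             slope = unname(coef(f)[2]),
                             intercept_hu = unname(coef(f)[1]), n = nrow(g))
                })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$module_type, res$kv), ]
  res$slope_ratio_vs_120kv <- NA_real_
  for (mt in unique(res$module_type)) {
    ref <- res$slope[res$module_type == mt & res$kv == 120]
    if (length(ref) == 1)
      res$slope_ratio_vs_120kv[res$module_type == mt] <-
        res$slope[res$module_type == mt] / ref
  }
  res
}

#' Contrast drift over repeated measurements
#'
#' Summarises repeated contrast measurements over acquisition dates: for
#' each contrast series (target contrast), the per-date mean and sd, the
#' grand mean across dates, and the sd of the per-date means.
#'
#' @param measurements See [contrast_measurements()]; must span at least
#'   two dates.
#' @return List with `per_date` (series x date means/sds) and `series`
#'   (grand mean and sd of means per series).
#' @export
drift_summary <- function(measurements) {
  if (length(unique(measurements$scan_date)) < 2)
    stop_ddcqa("drift analysis needs measurements on >= 2 dates")
  per_date <- do.call(rbind, lapply(
    split(measurements,
          list(measurements$target_contrast_hu, measurements$scan_date), drop = TRUE),
    function(g) data.frame(target_contrast_hu = g$target_contrast_hu[1],
                           scan_date = g$scan_date[1],
                           mean_hu = mean(g$measured_contrast_hu),
                           sd_hu = sd(g$measured_contrast_hu), n = nrow(g))))
  rownames(per_date) <- NULL
  series <- do.call(rbind, lapply(split(per_date, per_date$target_contrast_hu),
    function(g) data.frame(target_contrast_hu = g$target_contrast_hu[1],
                           grand_mean_hu = mean(g$mean_hu),
                           sd_of_means_hu = sd(g$mean_hu), n_dates = nrow(g))))
  rownames(series) <- NULL
  list(per_date = per_date, series = series)
}
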