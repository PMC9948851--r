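# Synthetic CT scans of a DDC module with ground truth.
#
# The rendering pipeline is: supersampled rasterization of the noiseless HU
# map (partial-volume edges), optional Gaussian PSF blur, then stationary
# white Gaussian noise whose standard deviation scales with the inverse
# square root of dose.

#' Acquisition settings for a simulated CT scan
#'
#' @param kv Tube voltage, one of 80, 100, 120, 140 kV.
#' @param ctdi_vol_mgy Volume CT dose index of the scan, mGy. The default
#'   corresponds to the maximal-current verification protocol at 120 kV.
#' @param pixel_spacing_mm In-plane pixel spacing, mm.
#' @param slice_thickness_mm Reconstructed slice thickness, mm.
#' @param n_slices Number of reconstructed slices through the module.
#' @param psf_fwhm_mm Full width at half maximum of the in-plane Gaussian
#'   point-spread function, mm; 0 disables blurring.
#' @param noise_sigma_ref_hu Noise standard deviation (HU) at the reference
#'   dose `ctdi_ref_mgy`; actual noise is
#'   `noise_sigma_ref_hu * sqrt(ctdi_ref_mgy / ctdi_vol_mgy)`.
#' @param ctdi_ref_mgy Reference dose for `noise_sigma_ref_hu`, mGy.
#' @param kernel_label Reconstruction kernel label (metadata only; kernel
#'   MTF differences are not modelled).
#' @param scan_date Acquisition date (used by the drift analysis).
#' @param kv_response Named numeric vector giving the multiplicative
#'   contrast response of the NaI (contrast-agent) rods per tube voltage,
#'   normalised to 1 at 120 kV. Iodine attenuates more strongly at low kV,
#'   so contrast rises as voltage falls; native (sucrose) rods are
#'   unaffected. The defaults are plausible placeholders and should be
#'   calibrated per scanner.
#' @return Object of class `ddc_acquisition`.
#' @export
acquisition_settings <- function(kv = 120, ctdi_vol_mgy = 40,
                                 pixel_spacing_mm = 0.5,
                                 slice_thickness_mm = 2, n_slices = 5,
                                 psf_fwhm_mm = 0.8,
                                 noise_sigma_ref_hu = 10, ctdi_ref_mgy = 20,
                                 kernel_label = "I30f",
                                 scan_date = as.Date("2020-01-01"),
                                 kv_response = c("80" = 1.30, "100" = 1.15,
                                                 "120" = 1.00, "140" = 0.90)) {
  if (!kv %in% c(80, 100, 120, 140))
    stop_ddcqa("unsupported tube voltage %s kV (supported: 80, 100, 120, 140)", format(kv))
  for (q in c(ctdi_vol_mgy = ctdi_vol_mgy, pixel_spacing_mm = pixel_spacing_mm,
              slice_thickness_mm = slice_thickness_mm, n_slices = n_slices,
              ctdi_ref_mgy = ctdi_ref_mgy))
    if (!is.finite(q) || q <= 0) stop_ddcqa("all physical settings must be positive")
  if (psf_fwhm_mm < 0 || noise_sigma_ref_hu < 0)
    stop_ddcqa("psf_fwhm_mm and noise_sigma_ref_hu must be non-negative")
  if (!as.character(kv) %in% names(kv_response))
    stop_ddcqa("kv_response has no entry for %s kV", format(kv))
  structure(list(kv = kv, ctdi_vol_mgy = ctdi_vol_mgy,
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 n_slices = as.integer(n_slices),
                 psf_fwhm_mm = psf_fwhm_mm,
                 noise_sigma_ref_hu = noise_sigma_ref_hu,
                 ctdi_ref_mgy = ctdi_ref_mgy, kernel_label = kernel_label,
                 scan_date = as.Date(scan_date), kv_response = kv_response),
            class = "ddc_acquisition")
}

#' Noise level implied by acquisition settings
#'
#' @param settings A `ddc_acquisition`.
#' @return Noise standard deviation in HU.
#' @export
noise_sigma <- function(settings) {
  settings$noise_sigma_ref_hu * sqrt(settings$ctdi_ref_mgy / settings$ctdi_vol_mgy)
}

# kV contrast-response factor for a module type (1 for native rods).
kv_factor <- function(settings, module_type) {
  if (identical(module_type, "contrast_agent"))
    unname(settings$kv_response[as.character(settings$kv)])
  else 1
}

# Map module-local mm to image (row, col) pixel coordinates.
# Convention: 0-based pixel indices are avoided; pixel centres sit at
# integer (row, col) in 1-based R indexing. Module x maps to +col, module y
# to -row (y up on screen), after rotation by theta_deg.
module_to_px <- function(transform, x_mm, y_mm) {
  th <- transform$theta_deg * pi / 180
  xr <- x_mm * cos(th) - y_mm * sin(th)
  yr <- x_mm * sin(th) + y_mm * cos(th)
  list(row = transform$center_row - yr / transform$pixel_spacing_mm + transform$t_row,
       col = transform$center_col + xr / transform$pixel_spacing_mm + transform$t_col)
}

px_to_module <- function(transform, row, col) {
  xr <- (col - transform$center_col - transform$t_col) * transform$pixel_spacing_mm
  yr <- -(row - transform$center_row - transform$t_row) * transform$pixel_spacing_mm
  th <- -transform$theta_deg * pi / 180
  list(x_mm = xr * cos(th) - yr * sin(th), y_mm = xr * sin(th) + yr * cos(th))
}

make_transform <- function(theta_deg, center_row, center_col, pixel_spacing_mm,
                           t_row = 0, t_col = 0, ncc = NA_real_) {
  list(theta_deg = theta_deg, center_row = center_row, center_col = center_col,
       pixel_spacing_mm = pixel_spacing_mm, t_row = t_row, t_col = t_col,
       ncc = ncc)
}

# Fractional pixel coverage of a disc, by ss x ss supersampling of each
# pixel in the disc's bounding box. Returns rows/cols/coverage vectors.
disc_coverage <- function(c_row, c_col, radius_px, nrow_img, ncol_img, ss = 4) {
  r0 <- max(1L, floor(c_row - radius_px - 1)); r1 <- min(nrow_img, ceiling(c_row + radius_px + 1))
  c0 <- max(1L, floor(c_col - radius_px - 1)); c1 <- min(ncol_img, ceiling(c_col + radius_px + 1))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  off <- ((seq_len(ss) - 0.5) / ss) - 0.5
  cov <- matrix(0, length(rows), length(cols))
  for (dr in off) for (dc in off) {
    d2 <- outer((rows + dr - c_row)^2, (cols + dc - c_col)^2, `+`)
    cov <- cov + (d2 <= radius_px^2)
  }
  idx <- which(cov > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  list(row = rows[idx[, 1]], col = cols[idx[, 2]], coverage = cov[idx] / ss^2)
}

# Separable Gaussian blur with edge renormalisation (kernel mass is rescaled
# where it is truncated by the image border).
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2)); k <- k / sum(k)
  blur1 <- function(m) {  # along rows (dimension 1)
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m)); wt <- numeric(n)
    for (j in -r:r) {
      src <- (1:n) + j
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + k[j + r + 1] * m[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + k[j + r + 1]
    }
    acc / wt
  }
  t(blur1(t(blur1(mat))))
}

# Noiseless HU map of one slice plus ground-truth masks.
render_slice <- function(layout, settings, transform, nrow_img, ncol_img,
                         supersample = 4, base_hu = 60, body_hu = 120,
                         render_fiducials = TRUE) {
  sp <- settings$pixel_spacing_mm
  rows <- seq_len(nrow_img); cols <- seq_len(ncol_img)
  d2 <- outer((rows - transform$center_row - transform$t_row)^2,
              (cols - transform$center_col - transform$t_col)^2, `+`)
  barrel_r_px <- (layout$barrel_diameter_mm / 2) / sp
  # barrel edge with supersampled partial volume
  edge <- disc_coverage(transform$center_row + transform$t_row,
                        transform$center_col + transform$t_col,
                        barrel_r_px, nrow_img, ncol_img, supersample)
  img <- matrix(body_hu, nrow_img, ncol_img)
  img[cbind(edge$row, edge$col)] <- body_hu + (base_hu - body_hu) * edge$coverage
  f <- kv_factor(settings, layout$module_type)
  label <- matrix(0L, nrow_img, ncol_img)
  rods <- layout$rods
  ctr <- module_to_px(transform, rods$x_mm, rods$y_mm)
  if (any(ctr$row - rods$diameter_mm / 2 / sp < 1) ||
      any(ctr$row + rods$diameter_mm / 2 / sp > nrow_img) ||
      any(ctr$col - rods$diameter_mm / 2 / sp < 1) ||
      any(ctr$col + rods$diameter_mm / 2 / sp > ncol_img))
    stop_ddcqa("layout does not fit in the %d x %d px field of view", nrow_img, ncol_img)
  for (i in seq_len(nrow(rods))) {
    rpx <- rods$diameter_mm[i] / 2 / sp
    cv <- disc_coverage(ctr$row[i], ctr$col[i], rpx, nrow_img, ncol_img, supersample)
    ix <- cbind(cv$row, cv$col)
    img[ix] <- img[ix] + rods$contrast_hu[i] * f * cv$coverage
    inside <- cv$coverage > 0 &
      (cv$row - ctr$row[i])^2 + (cv$col - ctr$col[i])^2 <= rpx^2
    label[ix[inside, , drop = FALSE]] <- rods$rod_id[i]
  }
  if (render_fiducials && length(layout$fiducial_angles_deg)) {
    fr_px <- 1.5 / sp  # 1.5 mm notch radius, centred on the rim
    fang <- layout$fiducial_angles_deg
    fx <- (layout$barrel_diameter_mm / 2) * cos(fang * pi / 180)
    fy <- (layout$barrel_diameter_mm / 2) * sin(fang * pi / 180)
    fc <- module_to_px(transform, fx, fy)
    for (i in seq_along(fang)) {
      cv <- disc_coverage(fc$row[i], fc$col[i], fr_px, nrow_img, ncol_img, supersample)
      if (is.null(cv)) next
      ix <- cbind(cv$row, cv$col)
      img[ix] <- img[ix] + (-1000 - img[ix]) * cv$coverage  # air cutout
    }
  }
  # background: barrel interior clear of the rim margin and of rods dilated
  # by 2 mm (pixel-centre rule)
  pm <- px_to_module(transform,
                     rep(rows, times = ncol_img), rep(cols, each = nrow_img))
  bg <- matrix(sqrt(pm$x_mm^2 + pm$y_mm^2) <=
                 layout$barrel_diameter_mm / 2 - layout$edge_margin_mm,
               nrow_img, ncol_img)
  for (i in seq_len(nrow(rods))) {
    rpx <- (rods$diameter_mm[i] / 2 + 2) / sp
    cv <- disc_coverage(ctr$row[i], ctr$col[i], rpx + 1, nrow_img, ncol_img, 1)
    near <- (cv$row - ctr$row[i])^2 + (cv$col - ctr$col[i])^2 <= rpx^2
    bg[cbind(cv$row, cv$col)[near, , drop = FALSE]] <- FALSE
  }
  list(img = img, label = label, background = bg,
       centers = data.frame(rod_id = rods$rod_id, row_px = ctr$row, col_px = ctr$col),
       kv_factor = f)
}

#' Simulate a CT scan of a DDC module
#'
#' Renders the noiseless HU map of the module (epoxy base plus rods) with
#' supersampled partial-volume edges, applies an optional Gaussian PSF, and
#' adds dose-scaled white Gaussian noise per slice. Contrast-agent rods are
#' scaled by the per-kV response factor of `settings`; native rods are not.
#'
#' @param layout A [ddc_layout()].
#' @param settings An [acquisition_settings()].
#' @param seed Integer seed; identical seeds give bit-identical volumes.
#' @param rotation_deg In-plane rotation of the module in the scanner, deg.
#' @param field_px Image size in pixels (square); default fits the barrel
#'   with an 8-pixel margin.
#' @param supersample Subpixel sampling factor per axis for rasterization.
#' @param base_hu HU of the epoxy base material (about 60 HU at 120 kV).
#' @param body_hu HU of the surrounding PMMA body.
#' @return Object of class `ddc_scan`: `volume` (rows x cols x slices HU
#'   array), `settings`, `layout`, `transform` (true module-to-pixel
#'   mapping), and `truth` with per-rod masks (`rod_label` matrix),
#'   `background` mask, rod centres in px and rendered (kV-scaled)
#'   contrasts.
#' @export
simulate_volume <- function(layout, settings, seed = 1, rotation_deg = 0,
                            field_px = NULL, supersample = 4,
                            base_hu = 60, body_hu = 120) {
  stopifnot(inherits(layout, "ddc_layout"), inherits(settings, "ddc_acquisition"))
  sp <- settings$pixel_spacing_mm
  if (is.null(field_px))
    field_px <- ceiling(layout$barrel_diameter_mm / sp) + 16L
  ctr <- (field_px + 1) / 2
  transform <- make_transform(rotation_deg, ctr, ctr, sp)
  rs <- render_slice(layout, settings, transform, field_px, field_px,
                     supersample, base_hu, body_hu)
  sigma_psf_px <- settings$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / sp
  clean <- gaussian_blur(rs$img, sigma_psf_px)
  sigma <- noise_sigma(settings)
  vol <- array(0, dim = c(field_px, field_px, settings$n_slices))
  with_seed(seed, {
    for (s in seq_len(settings$n_slices))
      vol[, , s] <- clean + if (sigma > 0) rnorm(length(clean), 0, sigma) else 0
  })
  rods <- layout$rods
  truth <- list(rod_label = rs$label, background = rs$background,
                rods = data.frame(rod_id = rods$rod_id,
                                  diameter_mm = rods$diameter_mm,
                                  target_contrast_hu = rods$contrast_hu,
                                  rendered_contrast_hu = rods$contrast_hu * rs$kv_factor,
                                  row_px = rs$centers$row_px,
                                  col_px = rs$centers$col_px))
  structure(list(volume = vol, settings = settings, layout = layout,
                 transform = transform, truth = truth, base_hu = base_hu,
                 body_hu = body_hu, noise_sigma_hu = sigma, seed = as.integer(seed)),
            class = "ddc_scan")
}

#' @export
print.ddc_scan <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("Simulated DDC scan: %d x %d px, %d slice(s), %g kV, %.1f mGy, noise sd %.2f HU\n",
              d[1], d[2], d[3], x$settings$kv, x$settings$ctdi_vol_mgy, x$noise_sigma_hu))
  cat(sprintf("  module '%s' (%s), rotation %.1f deg\n",
              x$layout$module_id, x$layout$module_type, x$transform$theta_deg))
  invisible(x)
}
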