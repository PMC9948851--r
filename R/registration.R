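# Template registration: recover the module's in-plane rotation (and a
# small integer translation) by maximizing the normalized cross-correlation
# between a rendered noiseless template and the scan.

bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  r0 <- pmin(pmax(r0, 1L), nr - 1L); c0 <- pmin(pmax(c0, 1L), nc - 1L)
  i00 <- img[cbind(r0, c0)]; i01 <- img[cbind(r0, c0 + 1L)]
  i10 <- img[cbind(r0 + 1L, c0)]; i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

#' Register a module template to a scan
#'
#' Renders a noiseless template of the module at rotation 0 and searches a
#' rotation grid (step `rotation_step_deg`, with parabolic sub-step
#' refinement) and a small integer-translation window for the pose
#' maximizing the normalized cross-correlation (NCC) between template and
#' image, evaluated over pixels inside the barrel. Registration fails with
#' an error when the best NCC stays below `ncc_floor` (e.g. no module in
#' the field of view).
#'
#' @param scan A `ddc_scan`, or a bare HU matrix plus `layout`/`settings`.
#' @param layout,settings Required when `scan` is a bare matrix.
#' @param rotation_step_deg Rotation grid step, degrees (<= 0.5 for the
#'   advertised accuracy).
#' @param rotation_range_deg Length-2 vector of the searched rotation
#'   interval, degrees.
#' @param max_shift_px Half-width of the integer translation search window.
#' @param ncc_floor Minimum acceptable NCC.
#' @param max_points Cap on the number of barrel pixels used for the NCC
#'   (deterministic stride subsampling).
#' @return A module-to-pixel transform (list with `theta_deg`, `t_row`,
#'   `t_col`, `center_row`, `center_col`, `pixel_spacing_mm`, `ncc`).
#' @export
register_template <- function(scan, layout = NULL, settings = NULL,
                              rotation_step_deg = 0.5,
                              rotation_range_deg = c(0, 360),
                              max_shift_px = 3, ncc_floor = 0.4,
                              max_points = 8000) {
  if (inherits(scan, "ddc_scan")) {
    layout <- scan$layout; settings <- scan$settings
    mid <- ceiling(dim(scan$volume)[3] / 2)
    img <- scan$volume[, , mid]
  } else {
    img <- scan
    if (is.null(layout) || is.null(settings))
      stop_ddcqa("layout and settings are required with a bare image matrix")
  }
  sp <- settings$pixel_spacing_mm
  ctr_r <- (nrow(img) + 1) / 2; ctr_c <- (ncol(img) + 1) / 2
  t0 <- make_transform(0, ctr_r, ctr_c, sp)
  tmpl <- render_slice(layout, settings, t0, nrow(img), ncol(img),
                       supersample = 1, base_hu = 0, body_hu = 0)$img
  rows <- seq_len(nrow(img)); cols <- seq_len(ncol(img))
  d2 <- outer((rows - ctr_r)^2, (cols - ctr_c)^2, `+`)
  support <- which(d2 <= ((layout$barrel_diameter_mm / 2 - 1) / sp)^2, arr.ind = TRUE)
  if (nrow(support) > max_points)
    support <- support[seq(1, nrow(support), length.out = max_points), , drop = FALSE]
  tv <- tmpl[support]
  if (sd(tv) == 0) stop_ddcqa("degenerate template (constant over the barrel)")
  # The template was rendered at theta = 0, so sampling the image at the
  # theta-rotated position of each template pixel and correlating with the
  # template values scans over candidate rotations.
  dr <- support[, 1] - ctr_r; dc <- support[, 2] - ctr_c
  score <- function(theta, t_row = 0, t_col = 0) {
    th <- theta * pi / 180
    # image offsets of template pixels under rotation by theta about centre.
    # In (row, col) with y flipped, rotation by +theta (counter-clockwise in
    # module x/y) maps (dr, dc) -> (dr cos th - dc sin th, dr sin th + dc cos th)
    rr <- ctr_r + t_row + dr * cos(th) - dc * sin(th)
    cc <- ctr_c + t_col + dr * sin(th) + dc * cos(th)
    iv <- bilinear_sample(img, rr, cc)
    if (sd(iv) == 0) return(-1)
    stats::cor(tv, iv)
  }
  thetas <- seq(rotation_range_deg[1], rotation_range_deg[2],
                by = rotation_step_deg)
  thetas <- thetas[thetas < rotation_range_deg[2] | rotation_range_deg[2] -
                     rotation_range_deg[1] < 360]
  sc <- vapply(thetas, score, numeric(1))
  i <- which.max(sc)
  theta <- thetas[i]
  # parabolic sub-step refinement on the three neighbouring grid scores
  if (length(thetas) >= 3) {
    im <- if (i == 1) length(thetas) else i - 1L
    ip <- if (i == length(thetas)) 1L else i + 1L
    denom <- sc[im] - 2 * sc[i] + sc[ip]
    if (is.finite(denom) && denom < 0)
      theta <- theta + 0.5 * rotation_step_deg * (sc[im] - sc[ip]) / denom
  }
  best <- c(score(theta), 0, 0)
  if (max_shift_px > 0) {
    grid <- expand.grid(t_row = -max_shift_px:max_shift_px,
                        t_col = -max_shift_px:max_shift_px)
    ss <- mapply(function(a, b) score(theta, a, b), grid$t_row, grid$t_col)
    j <- which.max(ss)
    best <- c(ss[j], grid$t_row[j], grid$t_col[j])
  }
  if (best[1] < ncc_floor)
    stop_ddcqa("registration failure: best NCC %.3f is below the floor %.2f (is the module in the field of view?)",
               best[1], ncc_floor)
  log_stage("register", theta_deg = round(theta, 3), t_row = best[2],
            t_col = best[3], ncc = round(best[1], 4))
  make_transform(theta, ctr_r, ctr_c, sp, t_row = best[2], t_col = best[3],
                 ncc = best[1])
}
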