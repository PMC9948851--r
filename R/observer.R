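# Psychometric simulated observer.
#
# Human click sessions are emulated with a logistic psychometric function of
# a Rose-type detectability index d = contrast * diameter / noise_sd. This
# is a testability device: it produces sessions with the right qualitative
# structure (larger and higher-contrast rods are detected more often, more
# noise shifts detection thresholds up) without claiming to model human
# vision.

#' Psychometric parameters of the simulated observer
#'
#' @param threshold Detectability index `d = contrast_hu * diameter_mm /
#'   noise_sd_hu` at which detection probability is 50%.
#' @param width Logistic scale of the psychometric curve (same units as the
#'   index); must be positive.
#' @param false_click_rate Expected number of spurious background clicks per
#'   session (Poisson).
#' @return Object of class `ddc_psychometric`.
#' @export
psychometric_params <- function(threshold = 25, width = 5, false_click_rate = 0) {
  if (width <= 0) stop_ddcqa("psychometric width must be positive")
  if (false_click_rate < 0) stop_ddcqa("false_click_rate must be non-negative")
  structure(list(threshold = threshold, width = width,
                 false_click_rate = false_click_rate),
            class = "ddc_psychometric")
}

#' Detection probability of a rod for the simulated observer
#'
#' @param contrast_hu Rendered rod contrast, HU.
#' @param diameter_mm Rod diameter, mm.
#' @param noise_sigma_hu Image noise standard deviation, HU.
#' @param params A [psychometric_params()].
#' @return Probability in (0, 1).
#' @export
detection_probability <- function(contrast_hu, diameter_mm, noise_sigma_hu, params) {
  if (any(noise_sigma_hu <= 0)) stop_ddcqa("noise_sigma_hu must be positive")
  d <- contrast_hu * diameter_mm / noise_sigma_hu
  plogis((d - params$threshold) / params$width)
}

#' Simulate an observer click session
#'
#' Each rod is clicked independently with its psychometric detection
#' probability; clicks land on the rod centre. Optionally, spurious
#' background clicks are added at uniform positions inside the barrel.
#'
#' @param scan A `ddc_scan` (rendered contrasts are used) or a
#'   [ddc_layout()] (nominal contrasts are used).
#' @param noise_sigma_hu Noise level driving the psychometric index;
#'   defaults to the scan's own noise level when `scan` is a `ddc_scan`.
#' @param params A [psychometric_params()].
#' @param seed Integer seed.
#' @param observer_id Observer label stored in the session.
#' @return Object of class `ddc_session` with a `clicks` data frame
#'   (`x_mm`, `y_mm` module-local, `slice`), the display window metadata
#'   (ww 400 / wc 60), and the ids of truly clicked rods.
#' @export
simulate_observer <- function(scan, noise_sigma_hu = NULL,
                              params = psychometric_params(), seed = 1,
                              observer_id = "sim") {
  if (inherits(scan, "ddc_scan")) {
    layout <- scan$layout
    rods <- scan$truth$rods
    contrasts <- rods$rendered_contrast_hu
    if (is.null(noise_sigma_hu)) noise_sigma_hu <- scan$noise_sigma_hu
  } else if (inherits(scan, "ddc_layout")) {
    layout <- scan
    rods <- layout$rods
    contrasts <- rods$contrast_hu
    if (is.null(noise_sigma_hu))
      stop_ddcqa("noise_sigma_hu is required when simulating from a bare layout")
  } else stop_ddcqa("scan must be a ddc_scan or a ddc_layout")
  if (!nzchar(observer_id)) stop_ddcqa("observer_id must be non-empty")
  p <- detection_probability(contrasts, rods$diameter_mm, noise_sigma_hu, params)
  with_seed(seed, {
    hit <- runif(length(p)) < p
    xy <- layout$rods[match(rods$rod_id, layout$rods$rod_id), c("x_mm", "y_mm")]
    clicks <- data.frame(x_mm = xy$x_mm[hit], y_mm = xy$y_mm[hit], slice = 1L)
    n_false <- if (params$false_click_rate > 0) rpois(1, params$false_click_rate) else 0L
    if (n_false > 0) {
      rad <- (layout$barrel_diameter_mm / 2 - layout$edge_margin_mm) * sqrt(runif(n_false))
      ang <- runif(n_false, 0, 2 * pi)
      clicks <- rbind(clicks, data.frame(x_mm = rad * cos(ang),
                                         y_mm = rad * sin(ang), slice = 1L))
    }
  })
  structure(list(observer_id = observer_id, clicks = clicks,
                 window = c(ww = 400, wc = 60),
                 noise_sigma_hu = noise_sigma_hu, params = params,
                 clicked_rods = rods$rod_id[hit], seed = as.integer(seed)),
            class = "ddc_session")
}

#' @export
print.ddc_session <- function(x, ...) {
  cat(sprintf("Observer session '%s': %d click(s), noise sd %.2f HU\n",
              x$observer_id, nrow(x$clicks), x$noise_sigma_hu))
  invisible(x)
}

#' Simulate a set of DDC curves from repeated observer sessions
#'
#' Convenience wrapper that runs `n_sessions` independent simulated-observer
#' sessions per noise level, converts each to a DDC, and stacks the results
#' in the long curve format used by [ddc_fit()].
#'
#' @param layout A [ddc_layout()].
#' @param noise_sigmas_hu Numeric vector of noise levels, HU.
#' @param n_sessions Sessions per noise level.
#' @param params A [psychometric_params()].
#' @param seed Integer seed.
#' @return Data frame of DDC points with columns `observer`, `diameter_mm`,
#'   `delta_min_hu`, `noise_sigma_hu`, `scan_id`.
#' @export
simulate_ddc_curves <- function(layout, noise_sigmas_hu, n_sessions = 100,
                                params = psychometric_params(), seed = 1) {
  out <- vector("list", length(noise_sigmas_hu) * n_sessions)
  k <- 0L
  for (i in seq_along(noise_sigmas_hu)) {
    for (j in seq_len(n_sessions)) {
      ses <- simulate_observer(layout, noise_sigmas_hu[i], params,
                               seed = seed + 1000L * i + j,
                               observer_id = sprintf("sim%02d_%03d", i, j))
      mt <- match_clicks(ses, layout)
      cur <- extract_ddc(mt$detected_rods, layout, observer_id = ses$observer_id,
                         scan_id = sprintf("noise%.3g_%03d", noise_sigmas_hu[i], j))
      cur$noise_sigma_hu <- noise_sigmas_hu[i]
      k <- k + 1L
      out[[k]] <- cur
    }
  }
  do.call(rbind, out)
}
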