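# Click-session evaluation: click-to-rod assignment and extraction of the
# difference detail curve (minimal detected contrast per rod diameter).

#' Assign observer clicks to contrast rods
#'
#' A click is assigned to the rod whose footprint, dilated by
#' `tolerance_mm`, contains it; if several dilated footprints contain the
#' click, the rod with the nearest centre wins. Clicks contained by no
#' footprint are false clicks. Several clicks on one rod count once.
#'
#' @param session A `ddc_session`, or a data frame of clicks with columns
#'   `x_mm`/`y_mm` (module-local) or `row_px`/`col_px` (image pixels, which
#'   require `transform`).
#' @param layout A [ddc_layout()].
#' @param transform Optional module-to-pixel transform (as returned by
#'   [register_template()] or stored in a `ddc_scan`) used to convert pixel
#'   clicks to module coordinates.
#' @param tolerance_mm Dilation of each rod footprint when testing
#'   containment; the default 1 mm accepts clicks up to 1 mm outside the
#'   physical rod edge.
#' @return List with `detected_rods` (unique rod ids), `false_clicks`
#'   (data frame of unassigned clicks), and `assignments` (per-click rod id,
#'   `NA` for false clicks).
#' @export
match_clicks <- function(session, layout, transform = NULL, tolerance_mm = 1) {
  clicks <- if (inherits(session, "ddc_session")) session$clicks else as.data.frame(session)
  if (!nrow(clicks))
    return(list(detected_rods = integer(0),
                false_clicks = clicks, assignments = integer(0)))
  if (all(c("row_px", "col_px") %in% names(clicks))) {
    if (is.null(transform))
      stop_ddcqa("pixel clicks require a registration transform")
    mm <- px_to_module(transform, clicks$row_px, clicks$col_px)
    clicks$x_mm <- mm$x_mm; clicks$y_mm <- mm$y_mm
  }
  rods <- layout$rods
  dx <- outer(clicks$x_mm, rods$x_mm, `-`)
  dy <- outer(clicks$y_mm, rods$y_mm, `-`)
  dist <- sqrt(dx^2 + dy^2)                    # clicks x rods
  lim <- rods$diameter_mm / 2 + tolerance_mm
  inside <- sweep(dist, 2, lim, `<=`)
  assignments <- vapply(seq_len(nrow(clicks)), function(i) {
    cand <- which(inside[i, ])
    if (!length(cand)) return(NA_integer_)
    rods$rod_id[cand[which.min(dist[i, cand])]]
  }, integer(1))
  list(detected_rods = sort(unique(assignments[!is.na(assignments)])),
       false_clicks = clicks[is.na(assignments), , drop = FALSE],
       assignments = assignments)
}

#' Extract a difference detail curve from detected rods
#'
#' For every rod diameter `s`, the DDC value is the minimal nominal contrast
#' among detected rods of that diameter; diameters at which no rod was
#' detected are recorded as `NA` (the observer saw no object of that size).
#' False clicks never contribute.
#'
#' @param detected_rods Integer rod ids (from [match_clicks()]).
#' @param layout A [ddc_layout()].
#' @param observer_id Observer label.
#' @param kv,ctdi_vol_mgy,scan_id,date Acquisition metadata carried along.
#' @return Data frame (one row per diameter, `NA` = not seen) with columns
#'   `observer`, `diameter_mm`, `delta_min_hu`, `module_type`, `kv`,
#'   `ctdi_vol_mgy`, `scan_id`, `date`.
#' @export
extract_ddc <- function(detected_rods, layout, observer_id = "obs",
                        kv = NA, ctdi_vol_mgy = NA, scan_id = NA, date = NA) {
  rods <- layout$rods
  det <- rods[rods$rod_id %in% detected_rods, ]
  dmin <- vapply(rod_diameters(), function(s) {
    v <- det$contrast_hu[det$diameter_mm == s]
    if (length(v)) min(v) else NA_real_
  }, numeric(1))
  data.frame(observer = observer_id, diameter_mm = rod_diameters(),
             delta_min_hu = dmin, module_type = layout$module_type,
             kv = kv, ctdi_vol_mgy = ctdi_vol_mgy, scan_id = scan_id,
             date = date, stringsAsFactors = FALSE)
}

#' Read or write DDC curve tables
#'
#' The curve CSV is the interchange format between observer evaluations and
#' model fitting: columns `observer`, `diameter_mm`, `delta_min_hu` (empty =
#' diameter not seen), plus optional metadata columns (`module_type`, `kv`,
#' `ctdi_vol_mgy`, `scan_id`, `date`).
#'
#' @param path CSV file path.
#' @param curves Data frame of DDC points.
#' @return `read_curves()` returns the curve data frame.
#' @export
read_curves <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer", "diameter_mm", "delta_min_hu")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_ddcqa("curve table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  d$delta_min_hu <- suppressWarnings(as.numeric(d$delta_min_hu))
  d
}

#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  write.csv(curves, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write or read an observer session as JSON
#'
#' @param session A `ddc_session`.
#' @param path File path.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ddc_session"))
  obj <- unclass(session)
  obj$params <- unclass(obj$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$clicks <- as.data.frame(obj$clicks)
  obj$params <- structure(as.list(obj$params), class = "ddc_psychometric")
  structure(obj, class = "ddc_session")
}
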