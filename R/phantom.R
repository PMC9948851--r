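# Phantom geometry: elliptical PMMA body with two 80 mm module slots, and
# cylindrical DDC modules holding 30 low-contrast rods in epoxy.

#' Rod diameters and nominal contrasts of a DDC module
#'
#' A DDC module carries one rod per combination of six diameters and five
#' nominal contrasts over the epoxy base, 30 rods in total.
#'
#' @return Numeric vector of rod diameters (mm) or nominal rod contrasts
#'   (Hounsfield units above the epoxy base).
#' @export
rod_diameters <- function() c(3, 4, 5, 6, 8, 9)

#' @rdname rod_diameters
#' @export
rod_contrasts <- function() c(16, 32, 48, 64, 80)

#' Generate a randomized DDC module layout
#'
#' Places the 30 contrast rods (one per diameter x contrast combination) at
#' random, non-overlapping positions inside the 80 mm module barrel by
#' rejection sampling. Rods are kept clear of the barrel rim so that all
#' objects sit in a region of comparable signal-to-noise ratio, and clear of
#' each other by at least `min_gap`.
#'
#' @param seed Integer seed; the same seed always yields the same layout.
#' @param module_type `"native"` (sucrose-doped rods) or `"contrast_agent"`
#'   (NaI-doped rods, whose rendered contrast depends on tube voltage).
#' @param min_gap Minimum edge-to-edge distance between rods, mm.
#' @param edge_margin Minimum distance between a rod edge and the barrel
#'   rim, mm.
#' @param barrel_diameter,depth Module barrel diameter and depth, mm.
#' @param fiducial_angles Angular positions (degrees) of the eight rim
#'   cutouts used for automatic orientation detection.
#' @param barcode Integer module id engraved on the module face.
#' @param module_id Free-text module label.
#' @param max_attempts Rejection-sampling attempts allowed per rod before
#'   placement is declared infeasible.
#' @return An object of class `ddc_layout`: the rod table (`rods`, with
#'   `rod_id`, `diameter_mm`, `contrast_hu`, `x_mm`, `y_mm` in module-local
#'   coordinates, origin at the barrel centre, x right / y up) plus the
#'   geometric parameters above.
#' @examples
#' lay <- ddc_layout(seed = 1)
#' nrow(lay$rods)  # 30
#' @export
ddc_layout <- function(seed, module_type = c("native", "contrast_agent"),
                       min_gap = 1, edge_margin = 3,
                       barrel_diameter = 80, depth = 40,
                       fiducial_angles = seq(0, 315, by = 45),
                       barcode = NULL, module_id = NULL,
                       max_attempts = 1e5) {
  module_type <- match.arg(module_type)
  if (min_gap < 0 || edge_margin < 0)
    stop_ddcqa("min_gap and edge_margin must be non-negative")
  rods <- expand.grid(diameter_mm = rod_diameters(),
                      contrast_hu = rod_contrasts(),
                      KEEP.OUT.ATTRS = FALSE)
  # place large rods first: improves feasibility without changing the
  # distribution of any individual accepted position
  rods <- rods[order(-rods$diameter_mm, rods$contrast_hu), ]
  r <- rods$diameter_mm / 2
  rmax <- barrel_diameter / 2 - edge_margin - r
  if (any(rmax <= 0))
    stop_ddcqa("edge_margin %.1f mm leaves no room for a %.0f mm rod inside the %.0f mm barrel",
               edge_margin, max(rods$diameter_mm), barrel_diameter)
  x <- y <- numeric(nrow(rods))
  with_seed(seed, {
    for (i in seq_len(nrow(rods))) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        rad <- rmax[i] * sqrt(runif(1))
        ang <- runif(1, 0, 2 * pi)
        xi <- rad * cos(ang); yi <- rad * sin(ang)
        if (i == 1L ||
            all(sqrt((x[seq_len(i - 1)] - xi)^2 + (y[seq_len(i - 1)] - yi)^2) >=
                r[seq_len(i - 1)] + r[i] + min_gap)) {
          x[i] <- xi; y[i] <- yi; placed <- TRUE; break
        }
      }
      if (!placed)
        stop_ddcqa(paste0("could not place a %.0f mm rod after %d attempts: ",
                          "minimum-gap constraint (min_gap = %.1f mm) is infeasible ",
                          "at this packing density"),
                   rods$diameter_mm[i], max_attempts, min_gap)
    }
  })
  rods$x_mm <- x; rods$y_mm <- y
  rods <- rods[order(rods$diameter_mm, rods$contrast_hu), ]
  rods$rod_id <- seq_len(nrow(rods))
  rods <- rods[, c("rod_id", "diameter_mm", "contrast_hu", "x_mm", "y_mm")]
  rownames(rods) <- NULL
  structure(list(rods = rods, module_type = module_type,
                 barrel_diameter_mm = barrel_diameter, depth_mm = depth,
                 min_gap_mm = min_gap, edge_margin_mm = edge_margin,
                 fiducial_angles_deg = fiducial_angles,
                 barcode = if (is.null(barcode)) as.integer(seed) else as.integer(barcode),
                 module_id = if (is.null(module_id)) sprintf("module-%d", as.integer(seed)) else module_id,
                 seed = as.integer(seed)),
            class = "ddc_layout")
}

#' @export
print.ddc_layout <- function(x, ...) {
  cat(sprintf("DDC module layout '%s' (%s, barcode %d)\n",
              x$module_id, x$module_type, x$barcode))
  cat(sprintf("  barrel %.0f mm x %.0f mm deep, %d rods, min gap %.1f mm, edge margin %.1f mm\n",
              x$barrel_diameter_mm, x$depth_mm, nrow(x$rods),
              x$min_gap_mm, x$edge_margin_mm))
  invisible(x)
}

materials_env <- new.env(parent = emptyenv())

#' Rod material compositions
#'
#' Weight-percent compositions of the epoxy mixtures used to cast the
#' contrast rods: clear epoxy resin doped with a 1:1 NaI/water solution for
#' the contrast-agent module, or with sucrose for the native module. One row
#' per (module type, nominal contrast).
#'
#' @return Data frame with columns `module_type`, `target_hu`, `resin_pct`,
#'   `additive`, `additive_pct`.
#' @export
contrast_materials <- function() {
  if (is.null(materials_env$tab)) {
    path <- system.file("extdata", "contrast_materials.csv", package = "ddcqa",
                        mustWork = TRUE)
    materials_env$tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  materials_env$tab
}

#' Look up the casting mixture for a target contrast
#'
#' @param target_hu Nominal rod contrast in HU; one of 16, 32, 48, 64, 80.
#' @param module_type `"native"` or `"contrast_agent"`.
#' @return One-row data frame with the resin and additive weight fractions.
#' @export
lookup_mixture <- function(target_hu, module_type = c("native", "contrast_agent")) {
  module_type <- match.arg(module_type)
  tab <- contrast_materials()
  row <- tab[tab$module_type == module_type & tab$target_hu == target_hu, ]
  if (nrow(row) != 1L)
    stop_ddcqa("no mixture defined for target contrast %s HU in the %s module (valid: %s)",
               format(target_hu), module_type,
               paste(sort(unique(tab$target_hu)), collapse = ", "))
  rownames(row) <- NULL
  row
}

#' Effective diameter of an elliptical cross-section
#'
#' The effective diameter of an AP x LAT elliptical slice is
#' `sqrt(AP * LAT)` (the AAPM size-specific dose estimate convention).
#'
#' @param ap_cm,lat_cm Anterior-posterior and lateral extents in cm.
#' @return Effective diameter in cm.
#' @export
effective_diameter <- function(ap_cm, lat_cm) {
  if (any(ap_cm <= 0) || any(lat_cm <= 0))
    stop_ddcqa("AP and LAT extents must be positive")
  sqrt(ap_cm * lat_cm)
}

#' @rdname effective_diameter
#' @param overrides Optional named character vector of label overrides keyed
#'   by `"APxLAT"` (e.g. `c("24x32" = "27 cm")`), for sites that label a
#'   slice by convention rather than by nearest-cm rounding.
#' @return `effective_diameter_label()`: a label such as `"32 cm"`.
#' @export
effective_diameter_label <- function(ap_cm, lat_cm, overrides = NULL) {
  key <- sprintf("%gx%g", ap_cm, lat_cm)
  if (!is.null(overrides) && key %in% names(overrides)) return(unname(overrides[key]))
  sprintf("%.0f cm", round(effective_diameter(ap_cm, lat_cm)))
}

body_slice_sizes <- function()
  data.frame(ap_cm = c(16, 20, 24, 28, 30), lat_cm = c(22, 24, 32, 34, 34))

#' Body phantom configuration
#'
#' The body phantom is a stack of elliptical PMMA slices (4 cm deep each)
#' available in five sizes, with two 80 mm holes accepting DDC modules and a
#' central bore for dose measurement.
#'
#' @param ap_cm,lat_cm Slice extents in cm; must be one of the five
#'   manufactured sizes (16x22, 20x24, 24x32, 28x34, 30x34).
#' @param n_slices Number of stacked slices.
#' @param label_overrides Passed to [effective_diameter_label()].
#' @return Object of class `ddc_body` describing the stack.
#' @export
body_phantom <- function(ap_cm = 30, lat_cm = 34, n_slices = 3,
                         label_overrides = NULL) {
  sizes <- body_slice_sizes()
  if (!any(sizes$ap_cm == ap_cm & sizes$lat_cm == lat_cm))
    stop_ddcqa("no %g x %g cm slice exists; available: %s", ap_cm, lat_cm,
               paste(sprintf("%gx%g", sizes$ap_cm, sizes$lat_cm), collapse = ", "))
  structure(list(ap_cm = ap_cm, lat_cm = lat_cm, n_slices = n_slices,
                 slice_depth_cm = 4,
                 effective_diameter_cm = effective_diameter(ap_cm, lat_cm),
                 label = effective_diameter_label(ap_cm, lat_cm, label_overrides),
                 module_slots = 2L),
            class = "ddc_body")
}

#' @export
print.ddc_body <- function(x, ...) {
  cat(sprintf("Body phantom %g x %g cm (effective diameter %.1f cm, label %s), %d slice(s)\n",
              x$ap_cm, x$lat_cm, x$effective_diameter_cm, x$label, x$n_slices))
  invisible(x)
}

#' Write or read a module layout as JSON
#'
#' Coordinates are module-local millimetres, origin at the barrel centre,
#' x right / y up.
#'
#' @param layout A `ddc_layout`.
#' @param path File path.
#' @return `read_layout()` returns a `ddc_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "ddc_layout"))
  obj <- unclass(layout)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$rods <- as.data.frame(obj$rods)
  structure(obj, class = "ddc_layout")
}
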