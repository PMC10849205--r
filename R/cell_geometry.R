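

# Per-cell geometric measurement and morphology scoring, mirroring the
# manual boundary measurement step (area, bounding box, length, angle) and
# the visual morphology classes (regular vs unusual polygonal vs swollen).

#' Measure the geometry of one cell boundary
#'
#' Area by the shoelace formula, perimeter as vertex-chain length,
#' orientation from the second area moments of the polygon (best-fit
#' ellipse major axis), bounding box, and side count after merging
#' near-collinear vertices (5 degree turning-angle tolerance by default --
#' visually counted sides ignore collinear splits).
#'
#' @param roi a [cell_roi].
#' @param pixel_size_um micrometres per pixel.
#' @param collinear_tol_deg turning-angle tolerance for side counting.
#' @return data.frame (one row) with `cell_id`, `area_px2`, `area_um2`,
#'   `perimeter_um`, bounding box (`bbox_x`, `bbox_y`, `bbox_w`, `bbox_h`),
#'   `orientation_angle_deg` in `[0, 180)`, `n_vertices`.
#' @export
measure_cell <- function(roi, pixel_size_um = 1, collinear_tol_deg = 5) {
  validate_cell_roi(roi)
  poly <- roi$polygon
  a <- polygon_area(poly)
  if (a <= 0) stop("cell ", roi$cell_id, ": degenerate polygon (area 0)")
  per <- polygon_perimeter(poly)
  bb <- apply(poly, 2, range)
  merged <- merge_collinear(poly, collinear_tol_deg)

  # second area moments about the centroid (green-theorem forms)
  cen <- polygon_centroid(poly)
  x <- poly[, 1] - cen[1]; y <- poly[, 2] - cen[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  sgn <- sign(sum(cr))
  ixx <- sgn * sum(cr * (y^2 + y * yn + yn^2)) / 12
  iyy <- sgn * sum(cr * (x^2 + x * xn + xn^2)) / 12
  ixy <- sgn * sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  ang <- 0.5 * atan2(2 * ixy, iyy - ixx) * 180 / pi
  ang <- ang %% 180

  data.frame(
    cell_id = roi$cell_id,
    area_px2 = a,
    area_um2 = a * pixel_size_um^2,
    perimeter_um = per * pixel_size_um,
    bbox_x = bb[1, 1], bbox_y = bb[1, 2],
    bbox_w = bb[2, 1] - bb[1, 1], bbox_h = bb[2, 2] - bb[1, 2],
    orientation_angle_deg = ang,
    n_vertices = nrow(merged),
    stringsAsFactors = FALSE)
}

#' Classify cell morphology against its cohort
#'
#' Labels follow the visual scheme: `REGULAR` (5-6 sides, not swollen),
#' `UNUSUAL_POLYGON` (>= 7 sides, e.g. octagonal or nine-sided),
#' `SWOLLEN` (area at least `swelling_threshold` times the cohort median),
#' or `UNUSUAL_AND_SWOLLEN`. The swelling threshold has no published
#' numeric definition; 1.5x the cohort median is the package default and is
#' configurable.
#'
#' @param geom one-row data.frame from [measure_cell()].
#' @param cohort data.frame of [measure_cell()] rows (>= 5 cells) used for
#'   the median area.
#' @param swelling_threshold multiple of the cohort median area above
#'   which a cell counts as swollen.
#' @return data.frame (one row): `cell_id`, `swelling_index`, `morphology`.
#' @export
classify_morphology <- function(geom, cohort, swelling_threshold = 1.5) {
  if (nrow(cohort) < 5L)
    stop("cohort too small for a stable median (need >= 5 cells, have ",
         nrow(cohort), ")")
  med <- stats::median(cohort$area_px2)
  sw_idx <- geom$area_px2 / med
  unusual <- geom$n_vertices >= 7L
  swollen <- sw_idx >= swelling_threshold
  lab <- if (unusual && swollen) "UNUSUAL_AND_SWOLLEN"
  else if (unusual) "UNUSUAL_POLYGON"
  else if (swollen) "SWOLLEN"
  else "REGULAR"
  data.frame(cell_id = geom$cell_id, swelling_index = sw_idx,
             morphology = lab, stringsAsFactors = FALSE)
}
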