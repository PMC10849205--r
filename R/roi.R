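

#' Cell boundary ROI
#'
#' A closed polygon delimiting one RPE cell in the en-face plane plus its z
#' extent, mirroring the manual boundary marking step of flat-mount
#' analysis. Coordinates are continuous pixel coordinates, 0-based,
#' x = column, y = row; slice 0 is the apical-most slice (microvilli).
#'
#' @param cell_id unique cell identifier (string).
#' @param polygon n x 2 matrix of (x, y) vertices, implicitly closed.
#' @param z_top apical slice index (0-based).
#' @param z_bottom basal slice index; must be `> z_top`.
#' @return an object of class `cell_roi`.
#' @export
cell_roi <- function(cell_id, polygon, z_top, z_bottom) {
  polygon <- as_poly_matrix(polygon)
  obj <- structure(
    list(cell_id = as.character(cell_id), polygon = polygon,
         z_top = as.integer(z_top), z_bottom = as.integer(z_bottom)),
    class = "cell_roi")
  validate_cell_roi(obj)
  obj
}

validate_cell_roi <- function(roi) {
  if (!nzchar(roi$cell_id)) stop("cell_id must be non-empty")
  if (nrow(roi$polygon) < 3L)
    stop("cell ", roi$cell_id, ": polygon needs >= 3 vertices")
  if (!is_simple_polygon(roi$polygon))
    stop("cell ", roi$cell_id, ": polygon is self-intersecting")
  if (polygon_area(roi$polygon) <= 0)
    stop("cell ", roi$cell_id, ": polygon area must be > 0")
  if (is.na(roi$z_top) || is.na(roi$z_bottom) || roi$z_top < 0 ||
      roi$z_top >= roi$z_bottom)
    stop("cell ", roi$cell_id, ": need 0 <= z_top < z_bottom")
  invisible(roi)
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("cell_roi '%s': %d vertices, area %.1f px^2, z %d-%d\n",
              x$cell_id, nrow(x$polygon), polygon_area(x$polygon),
              x$z_top, x$z_bottom))
  invisible(x)
}

#' Read cell ROIs from a JSON file
#'
#' Expected schema:
#' `{"cells": [{"id": ..., "polygon": [[x, y], ...], "z_top": ..., "z_bottom": ...}]}`.
#' Every polygon is validated (simple, closed, positive area) and duplicate
#' ids are rejected.
#'
#' @param path JSON file path.
#' @return list of [cell_roi] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$cells)) stop("ROI file has no 'cells' field")
  rois <- lapply(doc$cells, function(cl) {
    poly <- do.call(rbind, lapply(cl$polygon, function(v) unlist(v)))
    cell_roi(cl$id, poly, cl$z_top, cl$z_bottom)
  })
  ids <- vapply(rois, function(r) r$cell_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate cell_id in ROI file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rois
}

#' Write cell ROIs to a JSON file
#'
#' @param rois list of [cell_roi] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  cells <- lapply(rois, function(r) {
    validate_cell_roi(r)
    list(id = r$cell_id,
         polygon = lapply(seq_len(nrow(r$polygon)),
                          function(i) as.numeric(r$polygon[i, ])),
         z_top = r$z_top, z_bottom = r$z_bottom)
  })
  jsonlite::write_json(list(cells = cells), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
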