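

# Apical-basal zonal analysis (C1-C4) and autofluorescence intensity
# reports (RGB-stack green histogram, plot profile, through-z totals).

#' Zone (C1-C4) of a z position within a cell's extent
#'
#' The cell's z extent is split into four equal-thickness zones, C1 apical
#' (slice 0 side) to C4 basal. Positions exactly on a zone boundary go to
#' the more apical zone.
#'
#' @param z z position (slice units, may be fractional centroids).
#' @param z_top,z_bottom apical and basal slice indices of the cell.
#' @return integer vector in 1..4 (C1..C4).
#' @export
zone_of_z <- function(z, z_top, z_bottom) {
  n <- z_bottom - z_top + 1
  rel <- z - (z_top - 0.5)
  zn <- ceiling(rel / (n / 4))
  as.integer(pmin(4, pmax(1, zn)))
}

#' Zonal dispersion profile of a cell's granules
#'
#' Assigns each granule to C1-C4 by its centroid z and tabulates counts
#' per family and zone; optionally adds the mean AF488 intensity of the
#' cell's voxels per zone.
#'
#' @param roi a [cell_roi].
#' @param granules data.frame of this cell's granules (needs `z`; `family`
#'   optional).
#' @param stack optional [zstack] for per-zone mean AF intensity.
#' @return list with `boundaries` (data.frame of zone z-intervals),
#'   `counts` (zone x family matrix, plus a `total` column) and
#'   `mean_af` (length-4 vector or NULL).
#' @export
assign_zones <- function(roi, granules, stack = NULL) {
  validate_cell_roi(roi)
  if (nrow(granules)) {
    bad <- granules$z < roi$z_top - 0.5 | granules$z > roi$z_bottom + 0.5
    if (any(bad))
      stop("granule ", paste(granules$granule_id[bad], collapse = ", "),
           ": z outside cell extent of ", roi$cell_id)
  }
  n <- roi$z_bottom - roi$z_top + 1
  lo <- roi$z_top - 0.5 + (0:3) * n / 4
  hi <- roi$z_top - 0.5 + (1:4) * n / 4
  boundaries <- data.frame(zone = paste0("C", 1:4), z_lo = lo, z_hi = hi)

  fam_levels <- c("MELANIN", "MELANOLIPOFUSCIN", "LIPOFUSCIN")
  counts <- matrix(0L, 4, length(fam_levels) + 1L,
                   dimnames = list(paste0("C", 1:4),
                                   c(fam_levels, "total")))
  if (nrow(granules)) {
    zn <- zone_of_z(granules$z, roi$z_top, roi$z_bottom)
    for (k in 1:4) {
      in_k <- zn == k
      counts[k, "total"] <- sum(in_k)
      if (!is.null(granules$family))
        for (f in fam_levels)
          counts[k, f] <- sum(in_k & granules$family == f)
    }
  }
  mean_af <- NULL
  if (!is.null(stack)) {
    af <- get_channel(stack, "AF488")
    cm <- cell_mask_bbox(roi, dim(af))
    zs <- roi$z_top:roi$z_bottom
    zn_slice <- zone_of_z(zs, roi$z_top, roi$z_bottom)
    mean_af <- vapply(1:4, function(k) {
      sl <- zs[zn_slice == k]
      if (!length(sl)) return(NA_real_)
      sub <- af[cm$ys + 1L, cm$xs + 1L, sl + 1L, drop = FALSE]
      mean(sub[array(cm$mask, dim(sub))])
    }, numeric(1))
  }
  list(boundaries = boundaries, counts = counts, mean_af = mean_af)
}

#' Green-channel histogram of the RGB-converted stack
#'
#' The AF488 channel maps to green in the RGB conversion (488 nm emission
#' is imaged in green; red and blue are synthesised as zeros when absent).
#' Returns the 256-bin histogram of green values over the analysis region;
#' 16-bit values are first rescaled bit-exactly by
#' `floor(v * 255 / 65535)`.
#'
#' @param stack a [zstack] with an `AF488` channel.
#' @param region optional logical mask `(y, x)` selecting pixels; default
#'   all.
#' @return integer vector of length 256 (counts for values 0..255).
#' @export
rgb_stack_histogram <- function(stack, region = NULL) {
  af <- get_channel(stack, "AF488")
  d <- dim(af)
  if (!is.null(region)) {
    if (!any(region)) stop("empty analysis region")
    af <- af[rep(region, d[3])]
  }
  v <- as.integer(af)
  if (stack$bit_depth == 16L) v <- (v * 255L) %/% 65535L
  tabulate(v + 1L, nbins = 256L)
}

#' Plot profile: mean green intensity per column
#'
#' ImageJ "Plot Profile" semantics for a rectangular selection: for every
#' image column of the region, the mean intensity over the region's rows
#' (and slices).
#'
#' @param stack a [zstack].
#' @param x0,x1,y0,y1 0-based inclusive pixel bounds of the rectangular
#'   selection (defaults: full frame).
#' @param slices optional 0-based slice indices (default all).
#' @return numeric vector of column means, named by column index.
#' @export
plot_profile <- function(stack, x0 = 0, x1 = NULL, y0 = 0, y1 = NULL,
                         slices = NULL) {
  af <- get_channel(stack, "AF488")
  d <- dim(af)
  if (is.null(x1)) x1 <- d[2] - 1L
  if (is.null(y1)) y1 <- d[1] - 1L
  if (x1 < x0 || y1 < y0) stop("zero-width selection")
  if (is.null(slices)) slices <- 0:(d[3] - 1L)
  sub <- af[(y0:y1) + 1L, (x0:x1) + 1L, slices + 1L, drop = FALSE]
  prof <- apply(sub, 2, mean)
  names(prof) <- x0:x1
  prof
}

#' Total autofluorescence of one cell through its full z extent
#'
#' Sums AF488 intensity over every voxel whose pixel centre lies inside
#' the cell polygon, from the apex to the base (all slices of the cell's z
#' extent), as intensity-voxel units. A background-subtracted variant uses
#' the histogram mode outside all cell polygons.
#'
#' @param stack a [zstack].
#' @param roi a [cell_roi].
#' @param background optional background estimate
#'   ([estimate_background()]); computed against `roi` alone when `NULL`.
#' @param .af pre-extracted AF488 array (internal fast path).
#' @return list: `total_af`, `total_af_bg_sub`, `per_slice_mean`,
#'   `n_voxels`.
#' @export
total_af <- function(stack, roi, background = NULL, .af = NULL) {
  validate_cell_roi(roi)
  af <- .af %||% get_channel(stack, "AF488")
  d <- dim(af)
  bb <- apply(roi$polygon, 2, range)
  if (bb[2, 1] < -0.5 || bb[2, 2] < -0.5 || bb[1, 1] > d[2] - 0.5 ||
      bb[1, 2] > d[1] - 0.5)
    stop("cell ", roi$cell_id, ": ROI outside frame")
  cm <- cell_mask_bbox(roi, d)
  if (!any(cm$mask)) stop("cell ", roi$cell_id, ": empty cell mask")
  if (is.null(background))
    background <- estimate_background(stack, list(roi), "AF488")
  zs <- roi$z_top:roi$z_bottom
  sub <- af[cm$ys + 1L, cm$xs + 1L, zs + 1L, drop = FALSE]
  m3 <- array(cm$mask, dim(sub))
  n_in <- sum(cm$mask)
  total <- sum(sub[m3])
  per_slice <- vapply(seq_along(zs), function(i) {
    s <- sub[, , i, drop = FALSE]
    mean(s[cm$mask])
  }, numeric(1))
  names(per_slice) <- zs
  list(total_af = total,
       total_af_bg_sub = total - background$mode * n_in * length(zs),
       per_slice_mean = per_slice,
       n_voxels = n_in * length(zs))
}
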