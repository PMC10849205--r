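

#' Multi-channel z-stack container
#'
#' A `zstack` holds the voxel data of a multi-channel fluorescence z-stack
#' together with its physical calibration. Voxels are stored as a 4-D array
#' with dimensions `(y, x, z, channel)`; intensities are integers within the
#' declared bit depth. Channel names follow the acquisition convention:
#' `"AF488"` is the 488 nm-excitation autofluorescence channel (lipofuscin
#' bright), `"TRANS"` the transmitted-light channel (melanin dark), `"NUC"`
#' an optional nuclei channel.
#'
#' @param voxels numeric 4-D array `(y, x, z, channel)` of non-negative
#'   integers.
#' @param pixel_size_um micrometres per pixel in x and y (square pixels).
#' @param z_step_um micrometres per z slice.
#' @param channel_names character vector naming the 4th dimension.
#' @param bit_depth 8 or 16.
#' @return an object of class `zstack`.
#' @export
zstack <- function(voxels, pixel_size_um, z_step_um, channel_names,
                   bit_depth = 8L) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 4L)
  storage.mode(voxels) <- "double"
  obj <- structure(
    list(voxels = voxels,
         pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um),
         channel_names = as.character(channel_names),
         bit_depth = as.integer(bit_depth)),
    class = "zstack")
  validate_zstack(obj)
  obj
}

validate_zstack <- function(x) {
  d <- dim(x$voxels)
  if (length(x$channel_names) != d[4])
    stop("channel_names length (", length(x$channel_names),
         ") does not match channel dimension (", d[4], ")")
  if (anyDuplicated(x$channel_names))
    stop("duplicate channel names")
  if (!is.finite(x$pixel_size_um) || x$pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!is.finite(x$z_step_um) || x$z_step_um <= 0)
    stop("z_step_um must be > 0")
  if (!x$bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16")
  rng <- range(x$voxels)
  if (rng[1] < 0 || rng[2] > 2^x$bit_depth - 1)
    stop("voxel intensities outside declared bit depth [0, ",
         2^x$bit_depth - 1, "]")
  invisible(x)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "zstack: %d x %d px, %d slices, channels [%s], %d-bit, %.3g um/px, %.3g um/slice\n",
    d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
    x$bit_depth, x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' @export
dim.zstack <- function(x) dim(x$voxels)

#' Extract one channel of a z-stack as a 3-D array
#'
#' @param stack a [zstack].
#' @param channel channel name.
#' @return numeric array `(y, x, z)`.
#' @export
get_channel <- function(stack, channel) {
  i <- match(channel, stack$channel_names)
  if (is.na(i))
    stop("channel '", channel, "' not present (have: ",
         paste(stack$channel_names, collapse = ", "), ")")
  stack$voxels[, , , i, drop = FALSE][, , , 1]
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-page TIFF z-stack with its JSON metadata sidecar
#'
#' Page ordering is z-major, channel-minor (`page = z * n_channels + c`),
#' declared in the sidecar written by [write_zstack()]. The sidecar
#' (`<path>.json`) supplies `pixel_size_um`, `z_step_um`, `channel_names`
#' and `bit_depth`; alternatively pass them via `metadata`.
#'
#' @param path TIFF file path.
#' @param metadata optional named list overriding/replacing the sidecar.
#' @return a [zstack].
#' @export
read_zstack <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(metadata)) {
    sp <- sidecar_path(path)
    if (!file.exists(sp))
      stop("metadata sidecar not found: ", sp,
           " (pass `metadata` explicitly if there is none)")
    metadata <- jsonlite::fromJSON(sp, simplifyVector = TRUE)
  }
  need <- c("pixel_size_um", "z_step_um", "channel_names")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing fields: ", paste(miss, collapse = ", "))
  bit_depth <- if (!is.null(metadata$bit_depth)) as.integer(metadata$bit_depth) else 8L

  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), shp))
      stop("format error: page ", k, " has shape ",
           paste(dim(pages[[k]]), collapse = "x"), ", expected ",
           paste(shp, collapse = "x"))
  }
  nc <- length(metadata$channel_names)
  if (length(pages) %% nc != 0)
    stop("page count ", length(pages), " not a multiple of channel count ", nc)
  nz <- length(pages) %/% nc
  vox <- array(0, dim = c(shp[1], shp[2], nz, nc))
  for (z in seq_len(nz)) for (ch in seq_len(nc))
    vox[, , z, ch] <- pages[[(z - 1L) * nc + ch]]
  zstack(vox, metadata$pixel_size_um, metadata$z_step_um,
         metadata$channel_names, bit_depth)
}

#' Write a z-stack to a multi-page TIFF plus JSON metadata sidecar
#'
#' @param stack a [zstack].
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  validate_zstack(stack)
  d <- dim(stack$voxels)
  maxval <- 2^stack$bit_depth - 1
  pages <- vector("list", d[3] * d[4])
  for (z in seq_len(d[3])) for (ch in seq_len(d[4]))
    pages[[(z - 1L) * d[4] + ch]] <- stack$voxels[, , z, ch] / maxval
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  meta <- list(pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               channel_names = stack$channel_names,
               bit_depth = stack$bit_depth,
               page_order = "z-major, channel-minor")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
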