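# Shared fixtures: tiny stacks and polygons built in code.

# blank single-cell stack with AF488/TRANS (+ optional NUC), constant
# backgrounds and no noise
blank_stack <- function(ny = 32, nx = 32, nz = 8, af_bg = 30,
                        trans_bg = 200, nuc = FALSE, bit_depth = 8L) {
  chans <- c("AF488", "TRANS", if (nuc) "NUC")
  vox <- array(0, c(ny, nx, nz, length(chans)))
  vox[, , , 1] <- af_bg
  vox[, , , 2] <- trans_bg
  if (nuc) vox[, , , 3] <- 20
  zstack(vox, pixel_size_um = 0.2, z_step_um = 0.5, channel_names = chans,
         bit_depth = bit_depth)
}

# paint a solid axis-aligned box into one channel of a zstack
paint_box <- function(stack, channel, x, y, z, value) {
  ci <- match(channel, stack$channel_names)
  stack$voxels[y + 1L, x + 1L, z + 1L, ci] <- value
  stack
}

rect_roi <- function(id = "c1", x0 = 0, y0 = 0, x1 = 31, y1 = 31,
                     z_top = 0, z_bottom = 7) {
  cell_roi(id, rbind(c(x0 - 0.5, y0 - 0.5), c(x1 + 0.5, y0 - 0.5),
                     c(x1 + 0.5, y1 + 0.5), c(x0 - 0.5, y1 + 0.5)),
           z_top, z_bottom)
}

# rasterised disc voxel set (one slice), 0-based coords
disc_voxels <- function(cx, cy, r, z = 0) {
  g <- expand.grid(x = floor(cx - r):ceiling(cx + r),
                   y = floor(cy - r):ceiling(cy + r))
  g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, ]
  cbind(y = g$y, x = g$x, z = z)
}

regular_polygon <- function(n, r = 10, cx = 0, cy = 0, phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# the default-condition scene used by several suites (memoised per run)
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(n_cells = 50, seed = 7, ...) {
  key <- paste(c(n_cells, seed, unlist(list(...))), collapse = "_")
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- simulate_scene(
      scene_config(n_cells = n_cells, seed = seed, ...))
  .scene_cache[[key]]
}

cached_analysis <- function(n_cells = 50, seed = 7, ...) {
  key <- paste(c("an", n_cells, seed, unlist(list(...))), collapse = "_")
  if (is.null(.scene_cache[[key]])) {
    scn <- cached_scene(n_cells, seed, ...)
    .scene_cache[[key]] <- analyze_scene(scn$stack, scn$rois)
  }
  .scene_cache[[key]]
}
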