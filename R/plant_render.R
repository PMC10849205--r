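

# Granule planting and scene rendering.
#
# Granules are planted per cell with Poisson counts (baseline rate x the
# dose/day trend multiplier of the granule's family), phenotypes drawn from
# the configured mix renormalised within family, z positions from zonal
# priors (melanin and melanolipofuscin centred in C1-C2, lipofuscin in C3),
# and (x, y) uniform inside the cell polygon with enough margin that the
# whole granule fits.

rtruncnorm1 <- function(mu, sd, lo, hi) {
  for (i in 1:200) {
    z <- stats::rnorm(1, mu, sd)
    if (z >= lo && z <= hi) return(z)
  }
  min(hi, max(lo, mu))
}

# per-phenotype geometry sampler; radii in px (xy) and slices (z)
sample_granule_shape <- function(phenotype) {
  switch(phenotype,
    L1 = { r <- stats::runif(1, 1.2, 2.2); list(rx = r, ry = r, theta = 0) },
    L2 = { r <- stats::runif(1, 1.3, 1.8); list(rx = r, ry = r, theta = 0) },
    ML1 = { r <- stats::runif(1, 2.8, 4.0); list(rx = r, ry = r, theta = 0) },
    ML2 = { r <- stats::runif(1, 2.8, 4.0); list(rx = r, ry = r, theta = 0) },
    M1 = { r <- stats::runif(1, 1.3, 2.2); list(rx = r, ry = r, theta = 0) },
    M2 = {
      a <- stats::runif(1, 2.6, 4.0)
      list(rx = a, ry = a / stats::runif(1, 2.2, 3.0),
           theta = stats::runif(1, 0, pi))
    })
}

#' Plant ground-truth granules into a cell mosaic
#'
#' @param config a [scene_config()].
#' @param mosaic result of [generate_mosaic()].
#' @return list with `granules` (one row per planted granule: position,
#'   radii, orientation, phenotype, family, zone) and `subdiscs`
#'   (constituent discs of L2 aggregates, used by the renderer).
#' @export
plant_granules <- function(config, mosaic) {
  set.seed(config$seed + 202L)
  mix <- config$phenotype_mix[PHENOTYPES]
  fam_of <- FAMILIES[PHENOTYPES]
  rows <- list(); sub_rows <- list()
  gid <- 0L
  for (k in seq_along(mosaic$rois)) {
    roi <- mosaic$rois[[k]]
    placed_x <- placed_y <- placed_z <- placed_rz <- placed_ext <- numeric(0)
    nz <- roi$z_bottom - roi$z_top + 1L
    z_lo <- roi$z_top; z_hi <- roi$z_bottom
    mu_apical <- roi$z_top - 0.5 + 0.25 * nz   # mid C1-C2
    mu_mid <- roi$z_top - 0.5 + 0.625 * nz     # mid C3
    for (family in c("LIPOFUSCIN", "MELANOLIPOFUSCIN", "MELANIN")) {
      phen_in_fam <- PHENOTYPES[fam_of == family]
      p_fam <- sum(mix[phen_in_fam])
      if (p_fam <= 0) next
      rate <- config$granule_rate_per_cell * p_fam *
        trend_multiplier(config$trend_table, config$dose, config$day, family)
      n_g <- stats::rpois(1, rate)
      if (n_g == 0L) next
      phens <- sample(phen_in_fam, n_g, replace = TRUE,
                      prob = mix[phen_in_fam] / p_fam)
      for (ph in phens) {
        shape <- sample_granule_shape(ph)
        margin <- max(shape$rx, shape$ry) + 1
        rz_try <- stats::runif(1, 0.9, 1.3)
        if (family == "LIPOFUSCIN") {
          z <- rtruncnorm1(mu_mid, config$zonal_sd_lip, z_lo, z_hi)
        } else {
          z <- rtruncnorm1(mu_apical, config$zonal_sd_mel, z_lo, z_hi)
        }
        # granules are solid organelles: excluded volume keeps this one
        # clear of those already placed in the cell (in xy when the z
        # spans overlap); after 100 attempts the last draw is kept
        xy <- c(NA_real_, NA_real_)
        for (attempt in 1:100) {
          cand <- sample_in_polygon(1, roi$polygon, margin = margin,
                                    max_tries = 50L)
          if (is.na(cand[1])) next
          ok <- TRUE
          if (length(placed_x)) {
            # rendered solids reach 1.3x their radii; separate the full
            # footprints so distinct granules stay distinct components
            near_z <- abs(placed_z - z) < 1.3 * (placed_rz + rz_try) + 0.5
            if (any(near_z)) {
              dxy <- sqrt((placed_x[near_z] - cand[1])^2 +
                            (placed_y[near_z] - cand[2])^2)
              ok <- all(dxy >= 1.3 * (placed_ext[near_z] + margin - 1) + 1)
            }
          }
          xy <- cand
          if (ok) break
        }
        if (is.na(xy[1])) { # cell too small for this granule
          warning("cell ", roi$cell_id,
                  ": could not place a granule after 100 attempts; skipped")
          next
        }
        rz <- rz_try
        gid <- gid + 1L
        id <- sprintf("g_%05d", gid)
        if (ph == "L2") {
          # irregular aggregate: a jittered chain of overlapping discs,
          # long enough that the union reads as elongated/irregular
          n_sub <- sample(4:5, 1)
          dir <- stats::runif(1, 0, pi)
          step <- 1.55 * shape$rx
          offs <- (seq_len(n_sub) - (n_sub + 1) / 2) * step
          dxs <- offs * cos(dir) + stats::rnorm(n_sub, 0, 0.6)
          dys <- offs * sin(dir) + stats::rnorm(n_sub, 0, 0.6)
          sub_rows[[length(sub_rows) + 1L]] <- data.frame(
            granule_id = id, dx = dxs, dy = dys, r = shape$rx)
          ext <- max(sqrt(dxs^2 + dys^2)) + shape$rx
        } else ext <- max(shape$rx, shape$ry)
        placed_x <- c(placed_x, xy[1]); placed_y <- c(placed_y, xy[2])
        placed_z <- c(placed_z, z); placed_rz <- c(placed_rz, rz)
        placed_ext <- c(placed_ext, ext)
        rows[[length(rows) + 1L]] <- list(
          id, roi$cell_id, ph, family, xy[1], xy[2], z,
          shape$rx, shape$ry, rz, shape$theta, ext,
          zone_of_z(z, roi$z_top, roi$z_bottom))
      }
    }
  }
  col_c <- function(i) vapply(rows, function(r) as.character(r[[i]]),
                              character(1))
  col_n <- function(i) vapply(rows, function(r) as.numeric(r[[i]]),
                              numeric(1))
  granules <- if (length(rows)) data.frame(
    granule_id = col_c(1), cell_id = col_c(2),
    phenotype = col_c(3), family = col_c(4),
    x = col_n(5), y = col_n(6), z = col_n(7),
    rx = col_n(8), ry = col_n(9), rz = col_n(10), theta = col_n(11),
    extent = col_n(12), zone = as.integer(col_n(13)),
    stringsAsFactors = FALSE)
  else
    data.frame(granule_id = character(0), cell_id = character(0),
               phenotype = character(0), family = character(0),
               x = numeric(0), y = numeric(0), z = numeric(0),
               rx = numeric(0), ry = numeric(0), rz = numeric(0),
               theta = numeric(0), extent = numeric(0), zone = integer(0))
  subdiscs <- if (length(sub_rows)) do.call(rbind, sub_rows) else
    data.frame(granule_id = character(0), dx = numeric(0),
               dy = numeric(0), r = numeric(0))
  list(granules = granules, subdiscs = subdiscs)
}

# bounding block of a soft-edged solid within an array of dim `d`;
# returns NULL when fully outside, else 1-based index vectors
solid_bbox <- function(d, cx, cy, cz, rxy, rz) {
  pad <- 1.3
  x0 <- max(0L, floor(cx - pad * rxy - 1)); x1 <- min(d[2] - 1L, ceiling(cx + pad * rxy + 1))
  y0 <- max(0L, floor(cy - pad * rxy - 1)); y1 <- min(d[1] - 1L, ceiling(cy + pad * rxy + 1))
  z0 <- max(0L, floor(cz - pad * rz - 1)); z1 <- min(d[3] - 1L, ceiling(cz + pad * rz + 1))
  if (x1 < x0 || y1 < y0 || z1 < z0) return(NULL)
  list(ys = (y0:y1) + 1L, xs = (x0:x1) + 1L, zs = (z0:z1) + 1L)
}

# composite a soft-edged 3-D ellipsoid into an extracted block (the caller
# assigns the block back, keeping the big array modified in place), pulling
# voxel values toward `target`; ML2 gets a dark core via `core_target`
composite_solid <- function(blk, b, cx, cy, cz, rx, ry, rz, theta, target,
                            core_target = NULL, core_frac = 0.5) {
  ys <- b$ys - 1L; xs <- b$xs - 1L; zs <- b$zs - 1L # 0-based coords
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / rx
  v <- (-dx * sin(theta) + dy * cos(theta)) / ry
  ruv2 <- u^2 + v^2
  tgt <- matrix(target, length(ys), length(xs))
  if (!is.null(core_target)) tgt[sqrt(ruv2) <= core_frac] <- core_target
  for (zi in seq_along(zs)) {
    rho <- sqrt(ruv2 + ((zs[zi] - cz) / rz)^2)
    wgt <- pmax(0, pmin(1, (1.3 - rho) / 0.3))
    if (any(wgt > 0)) {
      sl <- blk[, , zi]
      blk[, , zi] <- sl + (tgt - sl) * wgt
    }
  }
  blk
}

# deterministic nuclei placement inside a cell (rejection sampling with
# shrinking radius); returns data.frame(x, y, r)
place_nuclei <- function(roi, n_nuclei, area) {
  r <- min(7, max(2.2, 0.16 * sqrt(area)))
  if (n_nuclei > 1L) r <- r * 0.85
  for (shrink in 1:6) {
    pts <- matrix(NA_real_, 0, 2)
    ok <- TRUE
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (t in 1:200) {
        p <- sample_in_polygon(1, roi$polygon, margin = r + 1)
        if (is.na(p[1])) next
        if (nrow(pts) == 0L ||
            min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= (2 * r + 2)^2) {
          pts <- rbind(pts, p); placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(data.frame(x = pts[, 1], y = pts[, 2], r = r))
    r <- r * 0.88
  }
  # fall back to whatever fits (may undercount downstream)
  warning("cell ", roi$cell_id, ": could not separate ", n_nuclei, " nuclei")
  data.frame(x = pts[, 1], y = pts[, 2], r = r)
}

#' Render a synthetic scene into a multi-channel z-stack
#'
#' Three channels are rendered. `AF488`: lipofuscin granules bright,
#' melanolipofuscin intermediate (ML2 as a bright ring with dark core),
#' melanosomes at background (melanin is not excited at 488 nm). `TRANS`:
#' melanin-containing granules dark below a bright background, lipofuscin
#' neutral; the basal quarter carries faint mitochondrial texture. `NUC`:
#' nuclei as bright discs. Granules are soft-edged 3-D solids spanning
#' about three slices; additive Gaussian noise (`noise_sd`) is applied and
#' values clipped to the bit depth.
#'
#' @param config a [scene_config()].
#' @param truth list with `mosaic` ([generate_mosaic()] result) and
#'   `granules`/`subdiscs` ([plant_granules()] result).
#' @return a [zstack] with channels `AF488`, `TRANS`, `NUC`.
#' @export
render_scene <- function(config, truth) {
  set.seed(config$seed + 303L)
  H <- config$image_size[1]; W <- config$image_size[2]
  nz <- config$n_slices
  af <- array(config$af_bg, c(H, W, nz))
  tr <- array(config$trans_bg, c(H, W, nz))
  nu <- array(config$nuc_bg, c(H, W, nz))

  d3 <- c(H, W, nz)
  g <- truth$granules
  if (nrow(g)) {
    for (i in seq_len(nrow(g))) {
      ph <- g$phenotype[i]
      if (ph == "L2") {
        sd_ <- truth$subdiscs[truth$subdiscs$granule_id == g$granule_id[i], ]
        for (s in seq_len(nrow(sd_))) {
          b <- solid_bbox(d3, g$x[i] + sd_$dx[s], g$y[i] + sd_$dy[s],
                          g$z[i], sd_$r[s], g$rz[i])
          if (!is.null(b))
            af[b$ys, b$xs, b$zs] <- composite_solid(
              af[b$ys, b$xs, b$zs, drop = FALSE], b,
              g$x[i] + sd_$dx[s], g$y[i] + sd_$dy[s], g$z[i],
              sd_$r[s], sd_$r[s], g$rz[i], 0, config$af_L)
        }
        next
      }
      b <- solid_bbox(d3, g$x[i], g$y[i], g$z[i], max(g$rx[i], g$ry[i]),
                      g$rz[i])
      if (is.null(b)) next
      if (ph == "L1") {
        af[b$ys, b$xs, b$zs] <- composite_solid(
          af[b$ys, b$xs, b$zs, drop = FALSE], b, g$x[i], g$y[i], g$z[i],
          g$rx[i], g$ry[i], g$rz[i], g$theta[i], config$af_L)
      } else if (ph %in% c("ML1", "ML2")) {
        af[b$ys, b$xs, b$zs] <- composite_solid(
          af[b$ys, b$xs, b$zs, drop = FALSE], b, g$x[i], g$y[i], g$z[i],
          g$rx[i], g$ry[i], g$rz[i], g$theta[i],
          if (ph == "ML1") config$af_ML1 else config$af_ML2_ring,
          core_target = if (ph == "ML2") config$af_ML2_core,
          core_frac = 0.5)
        tr[b$ys, b$xs, b$zs] <- composite_solid(
          tr[b$ys, b$xs, b$zs, drop = FALSE], b, g$x[i], g$y[i], g$z[i],
          g$rx[i], g$ry[i], g$rz[i], g$theta[i], config$trans_dark)
      } else { # M1, M2: dark in TRANS, silent in AF488
        tr[b$ys, b$xs, b$zs] <- composite_solid(
          tr[b$ys, b$xs, b$zs, drop = FALSE], b, g$x[i], g$y[i], g$z[i],
          g$rx[i], g$ry[i], g$rz[i], g$theta[i], config$trans_dark)
      }
    }
  }

  # nuclei (basal two-thirds of the stack)
  cells <- truth$mosaic$cells
  for (k in seq_len(nrow(cells))) {
    roi <- truth$mosaic$rois[[k]]
    np <- place_nuclei(roi, cells$n_nuclei[k], cells$area_px2[k])
    cz <- roi$z_top - 0.5 + 0.65 * (roi$z_bottom - roi$z_top + 1)
    for (s in seq_len(nrow(np))) {
      b <- solid_bbox(d3, np$x[s], np$y[s], cz, np$r[s], 1.6)
      if (!is.null(b))
        nu[b$ys, b$xs, b$zs] <- composite_solid(
          nu[b$ys, b$xs, b$zs, drop = FALSE], b, np$x[s], np$y[s], cz,
          np$r[s], np$r[s], 1.6, 0, config$nuc_fg)
    }
  }

  # faint basal texture standing in for mitochondria (region C4)
  basal <- seq.int(floor(3 * nz / 4) + 1L, nz)
  tr[, , basal] <- tr[, , basal] +
    stats::rnorm(H * W * length(basal), 0, 3)

  maxval <- 2^config$bit_depth - 1
  clipv <- function(a) {
    a <- a + stats::rnorm(length(a), 0, config$noise_sd)
    array(pmin(maxval, pmax(0, round(a))), dim(a))
  }
  vox <- array(0, c(H, W, nz, 3))
  vox[, , , 1] <- clipv(af)
  vox[, , , 2] <- clipv(tr)
  vox[, , , 3] <- clipv(nu)
  zstack(vox, config$pixel_size_um, config$z_step_um,
         c("AF488", "TRANS", "NUC"), config$bit_depth)
}

#' Simulate a complete ground-truthed flat-mount scene
#'
#' Runs [generate_mosaic()], [plant_granules()] and [render_scene()] under
#' the seeds derived from `config$seed`. Identical configurations produce
#' byte-identical scenes.
#'
#' @param config a [scene_config()].
#' @return list with `stack` ([zstack]), `rois`, and `truth` (`cells`,
#'   `granules`, `subdiscs`, `config`).
#' @export
simulate_scene <- function(config) {
  mosaic <- generate_mosaic(config)
  planted <- plant_granules(config, mosaic)
  truth <- list(mosaic = mosaic, granules = planted$granules,
                subdiscs = planted$subdiscs, config = config)
  stack <- render_scene(config, truth)
  list(stack = stack, rois = mosaic$rois,
       truth = list(cells = mosaic$cells, granules = planted$granules,
                    subdiscs = planted$subdiscs, config = config))
}
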