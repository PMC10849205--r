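

# Cell-mosaic generation: Poisson-disk seed sampling, Voronoi tessellation
# by iterative half-plane clipping, optional adjacent-cell merging (swollen
# cells), and side-count adjustment. deldir-style libraries are not part of
# the package's dependency set, so the tessellation is built directly: each
# cell starts as the frame rectangle and is clipped against the
# perpendicular-bisector half-plane of every other seed.

# blue-noise seed points: dart throwing with a shrinking exclusion radius
poisson_disk <- function(n, width, height) {
  r <- 0.7 * sqrt(width * height / n)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    p <- c(stats::runif(1, 0, width), stats::runif(1, 0, height))
    ok <- nrow(pts) == 0L ||
      min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= r^2
    if (ok) pts <- rbind(pts, p)
    tries <- tries + 1L
    if (tries > 60L * n) { r <- r * 0.85; tries <- 0L }
  }
  unname(pts)
}

# clip polygon to half-plane {p : (p - m) . d <= 0} (Sutherland-Hodgman)
clip_halfplane <- function(poly, m, d) {
  n <- nrow(poly)
  sd_ <- (poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2]
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- sd_[i] <= 0; pj_in <- sd_[j] <= 0
    if (pi_in) out <- rbind(out, poly[i, ])
    if (pi_in != pj_in) {
      t <- sd_[i] / (sd_[i] - sd_[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

voronoi_cells <- function(seeds, width, height) {
  frame <- rbind(c(-0.5, -0.5), c(width - 0.5, -0.5),
                 c(width - 0.5, height - 0.5), c(-0.5, height - 0.5))
  n <- nrow(seeds)
  lapply(seq_len(n), function(i) {
    poly <- frame
    for (j in seq_len(n)) {
      if (j == i || nrow(poly) < 3L) next
      m <- (seeds[i, ] + seeds[j, ]) / 2
      d <- seeds[j, ] - seeds[i, ]
      poly <- clip_halfplane(poly, m, d)
    }
    poly
  })
}

# index of the edge of A shared (reversed) with an edge of B, or NULL
find_shared_edge <- function(A, B, tol = 1e-5) {
  nA <- nrow(A); nB <- nrow(B)
  for (i in seq_len(nA)) {
    i2 <- if (i == nA) 1L else i + 1L
    for (j in seq_len(nB)) {
      j2 <- if (j == nB) 1L else j + 1L
      if (max(abs(A[i, ] - B[j2, ])) < tol &&
          max(abs(A[i2, ] - B[j, ])) < tol)
        return(c(i, j))
    }
  }
  NULL
}

# union of two polygons sharing edge A[i]->A[i+1] == B[j+1]->B[j]
merge_adjacent <- function(A, B, ij) {
  nA <- nrow(A); nB <- nrow(B)
  i <- ij[1]; j <- ij[2]
  cyc <- function(k, n) ((k - 1L) %% n) + 1L
  a_chain <- A[cyc(seq(i + 1L, i + nA), nA), , drop = FALSE] # Q ... P
  if (nB > 2L) {
    b_inner <- B[cyc(seq(j + 2L, j + nB - 1L), nB), , drop = FALSE]
    rbind(a_chain, b_inner)
  } else a_chain
}

# Visvalingam simplification: drop the vertex whose removal cuts the least
# area, down to `target` vertices (convex polygons only shrink)
simplify_to <- function(poly, target) {
  while (nrow(poly) > max(3L, target)) {
    n <- nrow(poly)
    prv <- poly[c(n, 1:(n - 1)), , drop = FALSE]
    nxt <- poly[c(2:n, 1), , drop = FALSE]
    tri <- abs((poly[, 1] - prv[, 1]) * (nxt[, 2] - prv[, 2]) -
                 (nxt[, 1] - prv[, 1]) * (poly[, 2] - prv[, 2])) / 2
    poly <- poly[-which.min(tri), , drop = FALSE]
  }
  poly
}

# corner chamfering: replace the sharpest corner by two vertices, adding
# one side per round; cuts stay inside the original polygon
chamfer_to <- function(poly, target, frac = 0.3) {
  guard <- 0L
  while (nrow(poly) < target && guard < 32L) {
    guard <- guard + 1L
    n <- nrow(poly)
    ang <- turning_angles(poly)
    k <- which.max(ang)
    if (ang[k] < 12 * pi / 180) break # further cuts would merge away
    kp <- if (k == 1L) n else k - 1L
    kn <- if (k == n) 1L else k + 1L
    v <- poly[k, ]
    e1 <- poly[kp, ] - v; e2 <- poly[kn, ] - v
    t <- frac * min(sqrt(sum(e1^2)), sqrt(sum(e2^2)))
    p1 <- v + e1 / sqrt(sum(e1^2)) * t
    p2 <- v + e2 / sqrt(sum(e2^2)) * t
    poly <- rbind(poly[seq_len(k - 1L), , drop = FALSE], p1, p2,
                  if (k < n) poly[seq(k + 1L, n), , drop = FALSE])
  }
  poly
}

#' Generate a polygonal cell mosaic with ground truth
#'
#' Poisson-disk-sampled seed points are tessellated into Voronoi cells
#' clipped to the frame. A `swollen_frac` fraction of cells is formed by
#' merging adjacent Voronoi pairs (emulating enlarged, injury-responding
#' cells), each remaining cell's side count is adjusted toward a target
#' drawn from the configured side-count distribution (vertex removal to
#' lower, convex-corner chamfering to raise; both keep cells inside their
#' Voronoi region, so cells never overlap), and nucleus counts are drawn
#' from `nuclei_probs`.
#'
#' @param config a [scene_config()].
#' @return list with `rois` (list of [cell_roi]) and `cells` (data.frame:
#'   `cell_id`, `area_px2`, `side_count`, `target_sides`, `n_nuclei`,
#'   `swollen`).
#' @export
generate_mosaic <- function(config) {
  set.seed(config$seed + 101L)
  W <- config$image_size[2]; H <- config$image_size[1]
  n <- config$n_cells
  mp <- config$morphology_params
  if (!is.null(mp$mean_sides) && mp$mean_sides < 3)
    stop("infeasible side-count target (< 3)")

  if (n == 1L) {
    poly <- rbind(c(-0.5, -0.5), c(W - 0.5, -0.5),
                  c(W - 0.5, H - 0.5), c(-0.5, H - 0.5))
    polys <- list(poly)
    swollen <- FALSE
  } else {
    seeds <- poisson_disk(n, W, H)
    polys <- voronoi_cells(seeds, W, H)
    swollen <- rep(FALSE, n)
    # merge a fraction of adjacent pairs into swollen cells
    n_merge <- round(n * (mp$swollen_frac %||% 0))
    if (n_merge > 0L) {
      used <- rep(FALSE, n)
      order_i <- sample.int(n)
      merged_polys <- list(); merged_from <- integer(0)
      for (i in order_i) {
        if (length(merged_from) >= n_merge) break
        if (used[i]) next
        cand <- setdiff(which(!used), i)
        cand <- cand[sample.int(length(cand))]
        for (j in cand) {
          ij <- find_shared_edge(polys[[i]], polys[[j]])
          if (!is.null(ij)) {
            mpoly <- merge_adjacent(polys[[i]], polys[[j]], ij)
            if (nrow(mpoly) >= 3L && is_simple_polygon(mpoly)) {
              used[i] <- used[j] <- TRUE
              merged_polys <- c(merged_polys, list(mpoly))
              merged_from <- c(merged_from, i)
            }
            break
          }
        }
      }
      keep <- which(!used)
      polys <- c(polys[keep], merged_polys)
      swollen <- c(rep(FALSE, length(keep)), rep(TRUE, length(merged_polys)))
    }
  }

  n_out <- length(polys)
  # side-count targets; swollen (merged) cells keep their natural shape
  targets <- pmax(4L, pmin(12L, as.integer(round(
    stats::rnorm(n_out, mp$mean_sides %||% 6, mp$sd_sides %||% 1)))))
  if (n_out > 1L) {
    for (k in seq_len(n_out)) {
      if (swollen[k]) next
      p <- merge_collinear(polys[[k]])
      if (nrow(p) > targets[k]) p <- simplify_to(p, targets[k])
      else if (nrow(p) < targets[k]) p <- chamfer_to(p, targets[k])
      polys[[k]] <- p
    }
  }

  ids <- sprintf("cell_%03d", seq_len(n_out))
  rois <- lapply(seq_len(n_out), function(k)
    cell_roi(ids[k], polys[[k]], 0L, config$n_slices - 1L))
  n_nuc <- sample(1:4, n_out, replace = TRUE, prob = config$nuclei_probs)
  cells <- data.frame(
    cell_id = ids,
    area_px2 = vapply(polys, polygon_area, numeric(1)),
    side_count = vapply(polys, function(p) nrow(merge_collinear(p)),
                        integer(1)),
    target_sides = targets,
    n_nuclei = n_nuc,
    swollen = swollen,
    stringsAsFactors = FALSE)
  list(rois = rois, cells = cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
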