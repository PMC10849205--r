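

# Polygon primitives used across the package. Polygons are n x 2 matrices of
# (x, y) vertices in continuous pixel coordinates (0-based, pixel-centre,
# x = column, y = row), implicitly closed, stored without a repeated first
# vertex. Orientation is irrelevant unless noted.

#' Polygon area by the shoelace formula
#'
#' @param poly numeric matrix with columns x, y (implicitly closed).
#' @param signed if `TRUE` return the signed area (positive for
#'   counter-clockwise orientation in a y-down image coordinate system the
#'   sign flips; callers only rely on `abs`).
#' @return area in squared input units.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as_poly_matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  if (signed) a else abs(a)
}

#' Polygon perimeter (vertex-chain length)
#' @inheritParams polygon_area
#' @return perimeter in input units.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_poly_matrix(poly)
  d <- poly - poly[c(2:nrow(poly), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid (area-weighted)
#' @inheritParams polygon_area
#' @return numeric length-2 (x, y).
#' @export
polygon_centroid <- function(poly) {
  poly <- as_poly_matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

as_poly_matrix <- function(poly) {
  if (is.list(poly) && !is.data.frame(poly)) poly <- do.call(rbind, poly)
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  dimnames(poly) <- NULL
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("polygon must be an n x 2 matrix with n >= 3")
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (n > 3L && max(abs(poly[1, ] - poly[n, ])) < 1e-12)
    poly <- poly[-n, , drop = FALSE]
  poly
}

#' Even-odd point-in-polygon test
#'
#' Vectorised ray-casting with the even-odd rule. Points that lie exactly on
#' an edge count as inside, matching the package's pixel-membership
#' convention (a pixel belongs to a cell if its centre is inside or on the
#' boundary of the cell polygon).
#'
#' @param px,py point coordinates (equal-length vectors).
#' @inheritParams polygon_area
#' @param boundary_eps distance below which a point is treated as on the
#'   boundary (and therefore inside).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly, boundary_eps = 1e-9) {
  poly <- as_poly_matrix(poly)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  if (boundary_eps > 0 && !all(inside)) {
    # only points not already claimed need the (costlier) boundary test
    out <- which(!inside)
    on_edge <- point_segment_dist_min(px[out], py[out], poly) <= boundary_eps
    inside[out[on_edge]] <- TRUE
  }
  inside
}

# minimum distance from each point to the polygon boundary
point_segment_dist_min <- function(px, py, poly) {
  poly <- as_poly_matrix(poly)
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    l2 <- vx * vx + vy * vy
    if (l2 < 1e-300) {
      d <- sqrt((px - ax)^2 + (py - ay)^2)
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / l2))
      d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    }
    dmin <- pmin(dmin, d)
    j <- i
  }
  dmin
}

# do open segments (p1,p2) and (p3,p4) properly intersect or overlap?
segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < eps) 0 else sign(v)
  }
  on_seg <- function(a, b, c) { # collinear c on [a, b]?
    min(a[1], b[1]) - eps <= c[1] && c[1] <= max(a[1], b[1]) + eps &&
      min(a[2], b[2]) - eps <= c[2] && c[2] <= max(a[2], b[2]) + eps
  }
  d1 <- o(p3, p4, p1); d2 <- o(p3, p4, p2)
  d3 <- o(p1, p2, p3); d4 <- o(p1, p2, p4)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' Pairwise segment test; edges sharing a vertex are allowed to touch only
#' at that shared endpoint.
#'
#' @inheritParams polygon_area
#' @return logical scalar.
#' @export
is_simple_polygon <- function(poly) {
  poly <- as_poly_matrix(poly)
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share an endpoint by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                             poly[idx[j, 1], ], poly[idx[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Merge near-collinear polygon vertices
#'
#' Removes vertices whose turning angle is below `tol_deg`, so that a
#' hexagon with one edge split by a collinear midpoint still counts six
#' sides.
#'
#' @inheritParams polygon_area
#' @param tol_deg turning-angle tolerance in degrees.
#' @return polygon matrix with merged vertices.
#' @export
merge_collinear <- function(poly, tol_deg = 5) {
  poly <- as_poly_matrix(poly)
  repeat {
    n <- nrow(poly)
    if (n <= 3L) break
    ang <- turning_angles(poly)
    k <- which.min(ang)
    if (ang[k] >= tol_deg * pi / 180) break
    poly <- poly[-k, , drop = FALSE]
  }
  poly
}

# absolute turning angle (radians) at every vertex
turning_angles <- function(poly) {
  n <- nrow(poly)
  prv <- poly[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  v1 <- poly - prv
  v2 <- nxt - poly
  a1 <- atan2(v1[, 2], v1[, 1])
  a2 <- atan2(v2[, 2], v2[, 1])
  d <- abs(a2 - a1)
  pmin(d, 2 * pi - d)
}

# sample points uniformly inside a polygon, at least margin away from the
# boundary; batched rejection sampling over the bounding box
sample_in_polygon <- function(n, poly, margin = 0, max_tries = 100L) {
  poly <- as_poly_matrix(poly)
  bb <- apply(poly, 2, range)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    tried <- 0L
    while (tried < max_tries) {
      m <- min(64L, max_tries - tried)
      tried <- tried + m
      px <- stats::runif(m, bb[1, 1], bb[2, 1])
      py <- stats::runif(m, bb[1, 2], bb[2, 2])
      ok <- point_in_polygon(px, py, poly, boundary_eps = 0)
      if (margin > 0 && any(ok))
        ok[ok] <- point_segment_dist_min(px[ok], py[ok], poly) >= margin
      hit <- which(ok)
      if (length(hit)) { out[i, ] <- c(px[hit[1]], py[hit[1]]); break }
    }
  }
  out
}
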