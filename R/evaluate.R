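

#' Match detected granules to planted ground truth
#'
#' Greedy nearest-centroid assignment: candidate pairs within `max_xy`
#' pixels in-plane and `max_z` slices axially are matched in order of
#' increasing distance, one-to-one. Returns the matched pairs and the
#' resulting recall and precision.
#'
#' @param detected data.frame from [detect_granules()].
#' @param truth data.frame of planted granules (needs `x`, `y`, `z`,
#'   `phenotype`).
#' @param max_xy in-plane matching radius (px).
#' @param max_z axial matching radius (slices).
#' @return list: `pairs` (data.frame with detected/truth indices, the
#'   truth phenotype and the detected label if present), `recall`,
#'   `precision`, `n_detected`, `n_truth`.
#' @export
match_granules <- function(detected, truth, max_xy = 2, max_z = 1) {
  n_d <- nrow(detected); n_t <- nrow(truth)
  if (n_d == 0L || n_t == 0L)
    return(list(pairs = data.frame(), recall = ifelse(n_t == 0, NA, 0),
                precision = ifelse(n_d == 0, NA, 0),
                n_detected = n_d, n_truth = n_t))
  cand <- list()
  for (i in seq_len(n_d)) {
    dx <- truth$x - detected$x[i]
    dy <- truth$y - detected$y[i]
    dz <- abs(truth$z - detected$z[i])
    dxy <- sqrt(dx^2 + dy^2)
    ok <- which(dxy <= max_xy & dz <= max_z)
    if (length(ok))
      cand[[length(cand) + 1L]] <- data.frame(d = i, t = ok,
                                              dist = dxy[ok])
  }
  pairs <- data.frame(d = integer(0), t = integer(0), dist = numeric(0))
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dist), ]
    used_d <- logical(n_d); used_t <- logical(n_t)
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_d[cand$d[r]] && !used_t[cand$t[r]]) {
        keep[r] <- TRUE
        used_d[cand$d[r]] <- TRUE
        used_t[cand$t[r]] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  if (nrow(pairs)) {
    pairs$truth_phenotype <- truth$phenotype[pairs$t]
    if (!is.null(detected$label))
      pairs$detected_label <- detected$label[pairs$d]
  }
  list(pairs = pairs,
       recall = nrow(pairs) / n_t,
       precision = nrow(pairs) / n_d,
       n_detected = n_d, n_truth = n_t)
}
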