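

# Six-phenotype classification from shape and AF pattern, as an ordered
# decision list so every assignment carries an auditable rationale. All
# numeric thresholds are configuration defaults expressed relative to the
# AF488 background (the published scheme is qualitative: round, oval or
# elongated shape; monolithic vs aggregate; bull's-eye ring).

#' Classification parameters
#'
#' AF thresholds are background-relative z-scores (low/mid/high at 2/5/8
#' background MAD-sigmas by default), the ring threshold is 3 noise-sigmas,
#' and `a_big_quantile` sets the "large granule" area cut at the cohort's
#' 90th percentile.
#'
#' @param af_z_lo,af_z_mid,af_z_hi background-relative z-scores for the
#'   low / mid / high AF cuts.
#' @param ring_k ring-score threshold in units of the background sigma.
#' @param circ_irregular,circ_round_ml,circ_round circularity cut-offs
#'   (below = irregular for L2; minimum roundness for ML1; minimum
#'   roundness for L1/M1).
#' @param aspect_spindle minimum aspect ratio of spindle melanosomes (M2).
#' @param a_big_quantile cohort quantile defining a "large" area.
#' @return list of class `classify_params`.
#' @export
classify_params <- function(af_z_lo = 2, af_z_mid = 5, af_z_hi = 8,
                            ring_k = 3, circ_irregular = 0.6,
                            circ_round_ml = 0.7, circ_round = 0.8,
                            aspect_spindle = 2.0, a_big_quantile = 0.9) {
  structure(list(af_z_lo = af_z_lo, af_z_mid = af_z_mid, af_z_hi = af_z_hi,
                 ring_k = ring_k, circ_irregular = circ_irregular,
                 circ_round_ml = circ_round_ml, circ_round = circ_round,
                 aspect_spindle = aspect_spindle,
                 a_big_quantile = a_big_quantile),
            class = "classify_params")
}

#' Family of each phenotype label
#' @param label character vector of phenotype labels.
#' @return character vector of families.
#' @export
phenotype_family <- function(label) unname(FAMILIES[label])

#' Classify detected granules into the six phenotypes
#'
#' First-match decision list (thresholds resolved from `params` and the
#' AF background):
#' * R1 `ring_score >= T_ring` and `mean_af >= T_af_mid` -> `ML2`
#'   (bull's-eye melanolipofuscin)
#' * R2 `mean_af < T_af_lo` and `aspect_ratio >= 2` -> `M2` (spindle
#'   melanosome)
#' * R3 `mean_af < T_af_lo` and `circularity >= 0.8` -> `M1` (round
#'   melanosome)
#' * R4 `mean_af >= T_af_hi` and (`circularity < 0.6` or `area > A_big`)
#'   -> `L2` (irregular/large lipofuscin aggregate)
#' * R5 `mean_af >= T_af_hi` and `circularity >= 0.8` -> `L1` (monolithic
#'   lipofuscin)
#' * R6 intermediate AF, `circularity >= 0.7`, `area >= A_big` -> `ML1`
#'   (large round melanolipofuscin)
#' * R7 fallback: nearest rule prototype in normalised feature space; the
#'   rationale records `"fallback"`. Intermediate granules between pure
#'   melanosome and pure lipofuscin land here or in R6 rather than getting
#'   a seventh label.
#'
#' @param granules data.frame from [detect_granules()] (needs `mean_af`,
#'   `circularity`, `aspect_ratio`, `ring_score`, `area_px2`).
#' @param background AF background list (`mode`, `mad`) from
#'   [estimate_background()].
#' @param params a [classify_params()].
#' @param noise_sd noise scale for the ring threshold; defaults to the
#'   background MAD.
#' @param a_big absolute "large area" cut; default is the
#'   `a_big_quantile` quantile of `granules$area_px2`.
#' @return `granules` with `label`, `family` and `rationale` columns.
#' @export
classify_granules <- function(granules, background,
                              params = classify_params(),
                              noise_sd = NULL, a_big = NULL) {
  if (!nrow(granules)) {
    granules$label <- character(0)
    granules$family <- character(0)
    granules$rationale <- character(0)
    return(granules)
  }
  sigma <- background$mad # stats::mad is already sigma-consistent
  if (is.null(noise_sd)) noise_sd <- sigma
  t_lo <- background$mode + params$af_z_lo * sigma
  t_mid <- background$mode + params$af_z_mid * sigma
  t_hi <- background$mode + params$af_z_hi * sigma
  t_ring <- params$ring_k * noise_sd
  if (is.null(a_big))
    a_big <- stats::quantile(granules$area_px2, params$a_big_quantile,
                             names = FALSE)

  lab <- character(nrow(granules))
  rat <- character(nrow(granules))
  for (i in seq_len(nrow(granules))) {
    g <- granules[i, ]
    res <- classify_one(g$mean_af, g$circularity, g$aspect_ratio,
                        g$ring_score, g$area_px2,
                        t_lo, t_mid, t_hi, t_ring, a_big, params)
    lab[i] <- res$label
    rat[i] <- res$rationale
  }
  granules$label <- lab
  granules$family <- phenotype_family(lab)
  granules$rationale <- rat
  granules
}

classify_one <- function(mean_af, circ, aspect, ring, area,
                         t_lo, t_mid, t_hi, t_ring, a_big, params) {
  if (ring >= t_ring && mean_af >= t_mid)
    return(list(label = "ML2", rationale = "R1"))
  if (mean_af < t_lo && aspect >= params$aspect_spindle)
    return(list(label = "M2", rationale = "R2"))
  if (mean_af < t_lo && circ >= params$circ_round)
    return(list(label = "M1", rationale = "R3"))
  if (mean_af >= t_hi && (circ < params$circ_irregular || area > a_big))
    return(list(label = "L2", rationale = "R4"))
  if (mean_af >= t_hi && circ >= params$circ_round)
    return(list(label = "L1", rationale = "R5"))
  if (mean_af >= t_lo && mean_af < t_hi && circ >= params$circ_round_ml &&
      area >= a_big)
    return(list(label = "ML1", rationale = "R6"))
  # R7: nearest rule prototype in normalised feature space.
  # Features: AF position (relative to the lo/hi band), circularity,
  # aspect (log2), ring presence, area relative to a_big.
  feat <- c(af = (mean_af - t_lo) / max(t_hi - t_lo, 1e-9),
            circ = circ, aspect = log2(max(aspect, 1)),
            ring = as.numeric(ring >= t_ring),
            big = as.numeric(area >= a_big))
  protos <- rbind(
    ML2 = c(0.9, 0.8, 0, 1, 1),
    M2 = c(-0.3, 0.5, 1.3, 0, 0),
    M1 = c(-0.3, 0.95, 0, 0, 0),
    L2 = c(1.3, 0.5, 0.8, 0, 1),
    L1 = c(1.3, 0.95, 0, 0, 0),
    ML1 = c(0.5, 0.9, 0, 0, 0.5))
  dists <- sqrt(colSums((t(protos) - feat)^2))
  list(label = names(which.min(dists)), rationale = "fallback")
}

#' Family counts and the melanin-to-lipofuscin ratio
#'
#' Counts granules per family and computes the ratio of melanin-containing
#' granules to lipofuscin. The headline ratio includes melanolipofuscin in
#' the numerator (melanin + melanosome over lipofuscin); a strict
#' melanosome-only variant is reported alongside. The ratio is `Inf` when
#' there is no lipofuscin but a positive numerator, and `NA` (missing)
#' when both are zero.
#'
#' @param granules classified granule data.frame (with `family`).
#' @return one-row data.frame: `n_melanin`, `n_melanolipofuscin`,
#'   `n_lipofuscin`, `melanin_to_lipofuscin_ratio`,
#'   `melanosome_only_ratio`.
#' @export
family_counts <- function(granules) {
  if (nrow(granules) && (is.null(granules$family) ||
                         anyNA(granules$family)))
    stop("unclassified granule present; run classify_granules() first")
  n_m <- sum(granules$family == "MELANIN")
  n_ml <- sum(granules$family == "MELANOLIPOFUSCIN")
  n_l <- sum(granules$family == "LIPOFUSCIN")
  ratio_of <- function(num) {
    if (n_l > 0) num / n_l else if (num > 0) Inf else NA_real_
  }
  data.frame(n_melanin = n_m, n_melanolipofuscin = n_ml,
             n_lipofuscin = n_l,
             melanin_to_lipofuscin_ratio = ratio_of(n_m + n_ml),
             melanosome_only_ratio = ratio_of(n_m))
}
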