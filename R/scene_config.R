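

# Condition levels used throughout: sodium-iodate dose and days post
# injection.
DOSES <- c("LOW_40", "HIGH_60")
DAYS <- c(1L, 7L, 30L)

PHENOTYPES <- c("L1", "L2", "ML1", "ML2", "M1", "M2")
FAMILIES <- c(L1 = "LIPOFUSCIN", L2 = "LIPOFUSCIN",
              ML1 = "MELANOLIPOFUSCIN", ML2 = "MELANOLIPOFUSCIN",
              M1 = "MELANIN", M2 = "MELANIN")

#' Default dose-by-day rate multipliers for the synthetic generator
#'
#' Encodes the qualitative injury trends as Poisson-rate multipliers per
#' family: at the low dose both melanin and lipofuscin rise from day 1 to
#' day 30; at the high dose melanin falls monotonically and lipofuscin
#' peaks at day 7. These are generator fixtures, not measured values.
#'
#' @return data.frame with columns dose, day, melanin, lipofuscin.
#' @export
default_trend_table <- function() {
  data.frame(
    dose = rep(DOSES, each = 3),
    day = rep(DAYS, 2),
    melanin = c(1.0, 1.3, 1.8, 1.0, 0.7, 0.4),
    lipofuscin = c(1.0, 1.5, 2.2, 1.0, 1.4, 0.6))
}

# nucleus-count probabilities over 1..4 nuclei; the high-dose day-7
# override embeds the multinucleated giant-cell peak
default_nuclei_probs <- function(dose, day) {
  if (dose == "HIGH_60" && day == 7L) c(0.35, 0.45, 0.13, 0.07)
  else c(0.55, 0.43, 0.015, 0.005)
}

# polygon side-count distribution and swollen-cell (merged-pair) fraction;
# morphology change is maximal on day 1 in both doses
default_morphology_params <- function(dose, day) {
  key <- paste(dose, day)
  tab <- list(
    "LOW_40 1"  = list(mean_sides = 7.0, sd_sides = 1.0, swollen_frac = 0.06),
    "LOW_40 7"  = list(mean_sides = 6.3, sd_sides = 0.9, swollen_frac = 0.03),
    "LOW_40 30" = list(mean_sides = 6.2, sd_sides = 0.9, swollen_frac = 0.02),
    "HIGH_60 1"  = list(mean_sides = 7.5, sd_sides = 1.0, swollen_frac = 0.08),
    "HIGH_60 7"  = list(mean_sides = 6.8, sd_sides = 1.0, swollen_frac = 0.12),
    "HIGH_60 30" = list(mean_sides = 6.5, sd_sides = 1.0, swollen_frac = 0.05))
  tab[[key]]
}

#' Configuration for a synthetic RPE flat-mount scene
#'
#' Holds every knob of the generator: mosaic geometry, granule rates and
#' phenotype mix, per-condition trend multipliers, zonal placement priors,
#' rendering intensities and noise. Defaults emulate a 40x field at
#' 0.2 um/px with 12 slices of 0.5 um, 8-bit, granules of 0.4-1.5 um
#' diameter (2-8 px).
#'
#' @param n_cells number of cells in the mosaic.
#' @param image_size `(y, x)` frame size in pixels.
#' @param n_slices number of z slices.
#' @param pixel_size_um,z_step_um physical calibration.
#' @param dose `"LOW_40"` or `"HIGH_60"` (40 vs 60 mg/kg sodium iodate).
#' @param day 1, 7 or 30 (days post injection).
#' @param seed integer RNG seed; a fixed seed makes the whole scene
#'   byte-identical across runs.
#' @param granule_rate_per_cell baseline mean granules per cell before
#'   trend multipliers.
#' @param phenotype_mix named probability vector over
#'   `c("L1","L2","ML1","ML2","M1","M2")`, summing to 1.
#' @param trend_table data.frame as [default_trend_table()].
#' @param nuclei_probs probability vector over 1-4 nuclei, or `NULL` for
#'   the dose/day default.
#' @param morphology_params list with `mean_sides`, `sd_sides`,
#'   `swollen_frac`, or `NULL` for the dose/day default.
#' @param noise_sd additive Gaussian intensity noise (grey levels).
#' @param ... further overrides of rendering intensities (`af_bg`, `af_L`,
#'   `af_ML1`, `af_ML2_ring`, `af_ML2_core`, `trans_bg`, `trans_dark`,
#'   `nuc_bg`, `nuc_fg`), zonal priors (`zonal_sd_mel`, `zonal_sd_lip`)
#'   and `bit_depth`.
#' @return an object of class `scene_config` (a named list).
#' @export
scene_config <- function(n_cells = 50L,
                         image_size = c(512L, 512L),
                         n_slices = 12L,
                         pixel_size_um = 0.2,
                         z_step_um = 0.5,
                         dose = "LOW_40",
                         day = 1L,
                         seed = 1L,
                         granule_rate_per_cell = 20,
                         phenotype_mix = c(L1 = 0.22, L2 = 0.10,
                                           ML1 = 0.12, ML2 = 0.08,
                                           M1 = 0.33, M2 = 0.15),
                         trend_table = default_trend_table(),
                         nuclei_probs = NULL,
                         morphology_params = NULL,
                         noise_sd = 8,
                         ...) {
  dose <- match.arg(dose, DOSES)
  day <- as.integer(day)
  if (!day %in% DAYS) stop("day must be one of ", paste(DAYS, collapse = ", "))
  if (is.null(nuclei_probs)) nuclei_probs <- default_nuclei_probs(dose, day)
  if (is.null(morphology_params))
    morphology_params <- default_morphology_params(dose, day)
  cfg <- list(
    n_cells = as.integer(n_cells), image_size = as.integer(image_size),
    n_slices = as.integer(n_slices), pixel_size_um = pixel_size_um,
    z_step_um = z_step_um, dose = dose, day = day, seed = as.integer(seed),
    granule_rate_per_cell = granule_rate_per_cell,
    phenotype_mix = phenotype_mix, trend_table = trend_table,
    nuclei_probs = nuclei_probs, morphology_params = morphology_params,
    noise_sd = noise_sd,
    # rendering intensities (8-bit grey levels); all intensity values are
    # fixtures -- absolute per-phenotype brightness is not known
    af_bg = 30, af_L = 180, af_ML1 = 80,
    af_ML2_ring = 180, af_ML2_core = 40,
    trans_bg = 200, trans_dark = 80,
    nuc_bg = 20, nuc_fg = 160,
    # zonal placement priors (slice units): melanin/melanolipofuscin
    # centred mid C1-C2, lipofuscin centred mid C3
    zonal_sd_mel = 1.1, zonal_sd_lip = 0.7,
    bit_depth = 8L)
  extra <- list(...)
  bad <- setdiff(names(extra), names(cfg))
  if (length(bad)) stop("unknown scene_config fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(extra)] <- extra
  validate_scene_config(structure(cfg, class = "scene_config"))
}

validate_scene_config <- function(cfg) {
  if (abs(sum(cfg$phenotype_mix) - 1) > 1e-9)
    stop("phenotype_mix must sum to 1")
  if (!setequal(names(cfg$phenotype_mix), PHENOTYPES))
    stop("phenotype_mix must be named over ", paste(PHENOTYPES, collapse = ","))
  if (abs(sum(cfg$nuclei_probs) - 1) > 1e-9)
    stop("nuclei_probs must sum to 1")
  if (cfg$granule_rate_per_cell < 0) stop("granule rate must be >= 0")
  if (cfg$n_cells < 1L) stop("n_cells must be >= 1")
  if (prod(cfg$image_size) / cfg$n_cells < 200)
    stop("image too small: mean cell area would be below 200 px^2")
  if (!is.null(cfg$morphology_params$mean_sides) &&
      cfg$morphology_params$mean_sides < 3)
    stop("infeasible side-count target (< 3)")
  cfg
}

# trend multiplier for one family under (dose, day); melanolipofuscin
# follows the melanin multiplier (melanin-containing granules)
trend_multiplier <- function(trend_table, dose, day, family) {
  row <- trend_table[trend_table$dose == dose & trend_table$day == day, ]
  if (nrow(row) != 1L) stop("trend_table has no row for ", dose, " day ", day)
  if (family == "LIPOFUSCIN") row$lipofuscin else row$melanin
}
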