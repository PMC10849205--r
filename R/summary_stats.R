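

# Per-cell summaries (Count / Total area / Average size / % Area / Mean),
# richness labelling, nuclei counting, and the group statistics
# (repeated-measures one-way ANOVA with Tukey HSD; paired two-tailed
# t-test) with Prism-style significance codes.

#' Round to the printed precision of the summary tables
#'
#' Published summary tables print averages to 3 decimals, switching to 3
#' significant figures below 0.001. Rounding is round-half-even (the R
#' default), which reproduces every arithmetically consistent printed row.
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
round_printed <- function(x) {
  ifelse(!is.finite(x), x,
         ifelse(abs(x) < 1e-3, signif(x, 3), round(x, 3)))
}

#' Prism-style significance code for a p-value
#'
#' `ns` for p >= 0.05, then `*` < 0.05, `**` < 0.01, `***` < 0.001,
#' `****` < 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
significance_code <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

#' Summarise one cell's granule content
#'
#' Computes the table columns: `count`, `total_area` (summed maximal
#' cross-section areas, px^2 and um^2), `average_size = total_area /
#' count` (also at printed precision), `percent_area` (100 x total area /
#' cell area), and two "Mean" interpretations: `mean_intensity`
#' (volume-weighted mean AF of granule voxels, the ImageJ Summarize
#' reading) and `mean_count_per_cell` (the count itself, the caption
#' reading); both are emitted because the published header is ambiguous.
#' Family counts and ratios from [family_counts()] are appended.
#'
#' @param granules classified granules of one cell.
#' @param geometry one-row [measure_cell()] result for the cell.
#' @param dose,day condition labels carried into the row.
#' @param n_nuclei optional nucleus count carried into the row.
#' @return one-row data.frame (a cell summary).
#' @export
summarize_cell <- function(granules, geometry, dose = NA, day = NA,
                           n_nuclei = NA_integer_) {
  count <- nrow(granules)
  total_area <- if (count) sum(granules$area_px2) else 0
  avg <- if (count == 0L) NA_real_ else total_area / count
  pct <- 100 * total_area / geometry$area_px2
  mean_int <- if (count)
    sum(granules$mean_af * granules$volume_vox) / sum(granules$volume_vox)
  else NA_real_
  fam <- family_counts(granules)
  cbind(data.frame(
    cell_id = geometry$cell_id, dose = dose, day = day,
    count = count, total_area = total_area,
    total_area_um2 = total_area * (geometry$area_um2 / geometry$area_px2),
    average_size = avg, average_size_printed = round_printed(avg),
    percent_area = pct, mean_intensity = mean_int,
    mean_count_per_cell = count, n_nuclei = n_nuclei,
    cell_area_px2 = geometry$area_px2,
    stringsAsFactors = FALSE), fam)
}

#' Label cells granule-rich or granule-poor against their cohort
#'
#' A cell is `GRANULE_POOR` iff its melanin-to-lipofuscin ratio exceeds
#' the cohort median ratio AND its granule count is below the cohort
#' median count (low granule content indexed by high melanin:lipofuscin
#' ratio and low granule number); otherwise `GRANULE_RICH`. Cells with a
#' missing ratio are labelled from the count criterion alone and flagged.
#'
#' @param summaries data.frame of [summarize_cell()] rows (>= 5 cells).
#' @return `summaries` with `richness` and `richness_flag` columns.
#' @export
label_richness <- function(summaries) {
  if (nrow(summaries) < 5L)
    stop("cohort too small (need >= 5 cells, have ", nrow(summaries), ")")
  ratio <- summaries$melanin_to_lipofuscin_ratio
  med_ratio <- stats::median(ratio[is.finite(ratio)])
  med_count <- stats::median(summaries$count)
  flag <- !is.finite(ratio) & is.na(ratio)
  poor <- ifelse(is.na(ratio),
                 summaries$count < med_count,
                 ratio > med_ratio & summaries$count < med_count)
  summaries$richness <- ifelse(poor, "GRANULE_POOR", "GRANULE_RICH")
  summaries$richness_flag <- ifelse(flag, "ratio_missing", "")
  summaries
}

#' Count nuclei of one cell from the nuclei channel
#'
#' Maximum projection of the nuclei channel over the cell's z extent,
#' Otsu threshold (clamped above background) within the cell mask, hole
#' filling, connected components, and a minimum-area filter. Cells with
#' three or more nuclei are multinucleated giant cells.
#'
#' @param stack a [zstack] with a `NUC` channel.
#' @param roi a [cell_roi].
#' @param min_nucleus_area smallest component kept (px^2).
#' @param background optional background estimate for the `NUC` channel.
#' @param .nu pre-extracted nuclei-channel array (internal fast path).
#' @return list: `n_nuclei`, `giant` (`n_nuclei >= 3`).
#' @export
count_nuclei <- function(stack, roi, min_nucleus_area = 12,
                         background = NULL, .nu = NULL) {
  if (!"NUC" %in% stack$channel_names) {
    warning("no NUC channel; nuclei counting skipped")
    return(list(n_nuclei = NA_integer_, giant = NA))
  }
  nu <- .nu %||% get_channel(stack, "NUC")
  d <- dim(nu)
  maxval <- 2^stack$bit_depth - 1
  cm <- cell_mask_bbox(roi, d)
  if (!any(cm$mask)) stop("cell ", roi$cell_id, ": empty cell mask")
  zs <- roi$z_top:roi$z_bottom
  sub <- nu[cm$ys + 1L, cm$xs + 1L, zs + 1L, drop = FALSE]
  proj <- apply(sub, c(1, 2), max)
  if (is.null(background))
    background <- estimate_background(stack, list(roi), "NUC")
  thr <- max(otsu_threshold(proj[cm$mask], maxval),
             background$mode + 2 * background$mad)
  bin <- matrix(0, nrow(proj), ncol(proj))
  bin[cm$mask & proj > thr] <- 1
  bin <- EBImage::fillHull(bin)
  lbl <- EBImage::bwlabel(bin)
  sizes <- tabulate(lbl[lbl > 0])
  n <- sum(sizes >= min_nucleus_area)
  list(n_nuclei = n, giant = n >= 3L)
}

#' Repeated-measures one-way ANOVA with Tukey HSD
#'
#' Fits a within-subject one-way ANOVA (`value ~ level + Error(subject)`)
#' when every subject is observed once per level; pairwise comparisons use
#' the studentized-range distribution on the within-stratum mean square.
#' With incomplete or unshared subjects it falls back to an ordinary
#' one-way ANOVA with `TukeyHSD` and a warning (the design the data
#' actually permit).
#'
#' @param values numeric response.
#' @param levels factor (or coercible) of condition levels (>= 2, with
#'   >= 2 observations per level).
#' @param subjects within-subject identifiers aligned with `values`.
#' @return list of class `group_result`: `test`, `statistic` (F),
#'   `p_value`, `code`, `pairwise` (data.frame: comparison, diff,
#'   p_value, code).
#' @export
rm_anova_tukey <- function(values, levels, subjects = NULL) {
  lev <- factor(levels)
  k <- nlevels(lev)
  if (k < 2L) stop("need >= 2 levels")
  if (any(table(lev) < 2L)) stop("need >= 2 observations per level")
  complete_rm <- FALSE
  if (!is.null(subjects)) {
    sub <- factor(subjects)
    tab <- table(sub, lev)
    complete_rm <- all(tab == 1L)
  }
  if (complete_rm) {
    df <- data.frame(y = values, lev = lev, sub = sub)
    fit <- stats::aov(y ~ lev + Error(sub), data = df)
    s <- summary(fit)
    within <- s[["Error: Within"]][[1]]
    fval <- within["lev", "F value"]
    pval <- within["lev", "Pr(>F)"]
    mse <- within["Residuals", "Mean Sq"]
    dfe <- within["Residuals", "Df"]
    n_per <- nlevels(sub)
    means <- tapply(values, lev, mean)
    prs <- utils::combn(levels(lev), 2)
    pw <- data.frame(
      comparison = paste(prs[2, ], "vs", prs[1, ]),
      diff = means[prs[2, ]] - means[prs[1, ]],
      row.names = NULL)
    q <- abs(pw$diff) / sqrt(mse / n_per)
    pw$p_value <- stats::ptukey(q, k, dfe, lower.tail = FALSE)
    test <- "RM one-way ANOVA + Tukey"
  } else {
    if (!is.null(subjects))
      warning("subjects not shared across all levels; ",
              "falling back to ordinary one-way ANOVA")
    fit <- stats::aov(values ~ lev)
    s <- summary(fit)[[1]]
    fval <- s["lev", "F value"]
    pval <- s["lev", "Pr(>F)"]
    tk <- stats::TukeyHSD(fit)$lev
    pw <- data.frame(
      comparison = gsub("-", " vs ", rownames(tk), fixed = TRUE),
      diff = tk[, "diff"], p_value = tk[, "p adj"], row.names = NULL)
    test <- "one-way ANOVA + Tukey"
  }
  pw$code <- significance_code(pw$p_value)
  structure(list(test = test, statistic = unname(fval),
                 p_value = unname(pval),
                 code = significance_code(pval), pairwise = pw),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$code))
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Paired two-tailed t-test with significance code
#'
#' Pairs by position. Degenerate cases are handled explicitly: all
#' differences zero gives t = 0, p = 1; zero-variance non-zero differences
#' give an infinite t and p = 0 flagged as degenerate (the parametric
#' model has no spread to estimate).
#'
#' @param a,b equal-length numeric series (n >= 2).
#' @return `group_result` list: `test`, `statistic` (t), `df`, `p_value`,
#'   `code`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 2L) stop("need n >= 2 pairs")
  d <- a - b
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    degenerate <- TRUE
    if (all(d == 0)) { tstat <- 0; pval <- 1 }
    else { tstat <- sign(mean(d)) * Inf; pval <- 0 }
    dfree <- length(d) - 1L
  } else {
    ht <- stats::t.test(a, b, paired = TRUE)
    tstat <- unname(ht$statistic); pval <- ht$p.value
    dfree <- unname(ht$parameter)
  }
  structure(list(test = "Paired two-tailed t-test", statistic = tstat,
                 df = dfree, p_value = pval,
                 code = significance_code(pval), degenerate = degenerate,
                 pairwise = NULL),
            class = "group_result")
}
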