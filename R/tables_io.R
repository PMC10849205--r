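

# Tabular outputs and the published-table self-consistency audit.

#' Write per-cell summary tables to CSV
#'
#' Emits the canonical columns `Count`, `Total area`, `Average size`,
#' `% Area`, `Mean` alongside `cell_id`, `dose`, `day` and the
#' family-stratified counts, in a fixed column and row order (sorted by
#' dose, day, cell_id) so output is byte-identical across runs.
#'
#' @param summaries non-empty data.frame of [summarize_cell()] rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_tables <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("nothing to write: empty summary list")
  out <- data.frame(
    cell_id = summaries$cell_id,
    dose = summaries$dose,
    day = summaries$day,
    Count = summaries$count,
    `Total area` = summaries$total_area,
    `Average size` = summaries$average_size,
    `% Area` = summaries$percent_area,
    Mean = summaries$mean_intensity,
    mean_count_per_cell = summaries$mean_count_per_cell,
    total_area_um2 = summaries$total_area_um2,
    n_melanin = summaries$n_melanin,
    n_melanolipofuscin = summaries$n_melanolipofuscin,
    n_lipofuscin = summaries$n_lipofuscin,
    melanin_to_lipofuscin_ratio = summaries$melanin_to_lipofuscin_ratio,
    n_nuclei = summaries$n_nuclei,
    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$dose, out$day, out$cell_id), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Load the published group-summary fixture rows
#'
#' Transcribed group-level summary rows (count, total area, printed
#' average size per dose column and day) from a published RPE flat-mount
#' granule study, used by [audit_table_consistency()]. The `consistent`
#' flag marks rows whose printed average equals total/count at printed
#' precision; rows with animal-averaged fractional counts (and one row
#' with a corrupted count cell) are not arithmetically consistent and are
#' flagged `FALSE`.
#'
#' @return data.frame: `table`, `dose_mg`, `day`, `count`, `total_area`,
#'   `printed_average`, `consistent`.
#' @export
published_summary_rows <- function() {
  path <- system.file("extdata", "published_granule_summaries.csv",
                      package = "granulyzer")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Audit summary rows for the average = total/count identity
#'
#' Recomputes `average_size = total_area / count`, rounds it at printed
#' precision ([round_printed()]) and compares with the printed value.
#'
#' @param rows data.frame with `count`, `total_area`, `printed_average`.
#' @return `rows` with `recomputed` and `matches` columns.
#' @export
audit_table_consistency <- function(rows) {
  rows$recomputed <- round_printed(rows$total_area / rows$count)
  rows$matches <- abs(rows$recomputed - rows$printed_average) <=
    1e-9 * pmax(1, abs(rows$printed_average))
  rows
}
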