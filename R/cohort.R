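#' Combine per-sample junction scores into a cohort calling table
#'
#' For each junction, collects the empirical p-values across the samples of
#' an individual and takes their median — the junction's calling score — a
#' multiple-testing-robust summary: a junction that looks significant in one
#' sample by chance but is weak elsewhere ends up with a large median and is
#' not called. Only samples where the junction passed all four per-sample
#' filters contribute (`eligible_for_median`); the median of an even count is
#' the mean of the two central values. Junctions with no eligible sample get
#' a calling score of 1 (never called) and a reason flag.
#'
#' @param sample_tables A list of per-sample junction tibbles from
#'   [score_junctions()] (or one tibble already containing several samples).
#' @return Cohort tibble, one row per junction, sorted by junction key:
#'   `calling_score` (median eligible `emp_p`), `n_samples_detected`,
#'   `n_samples_eligible`, `reason`.
#' @export
combine_median <- function(sample_tables) {
  if (inherits(sample_tables, "data.frame")) sample_tables <- list(sample_tables)
  if (length(sample_tables) == 0L) stop("no per-sample tables supplied", call. = FALSE)
  df <- dplyr::bind_rows(sample_tables)
  if (nrow(df) == 0L) stop("per-sample tables are empty", call. = FALSE)
  df |>
    dplyr::group_by(.data$chrom, .data$intron_start, .data$intron_end) |>
    dplyr::summarise(
      strand = .consensus_strand(.data$strand),
      n_samples_detected = dplyr::n(),
      n_samples_eligible = sum(.data$eligible_for_median),
      calling_score = if (any(.data$eligible_for_median)) {
        stats::median(.data$emp_p[.data$eligible_for_median])
      } else 1,
      total_reads = sum(.data$N),
      .groups = "drop"
    ) |>
    dplyr::mutate(reason = ifelse(.data$n_samples_eligible == 0L,
                                  "no_eligible_sample", "")) |>
    dplyr::arrange(.data$chrom, .data$intron_start, .data$intron_end)
}

#' Call junctions from a cohort table at a score threshold
#'
#' A junction is called when its calling score (median empirical p-value) is
#' strictly below `threshold`. The default 0.15 balances sensitivity and
#' specificity for junction discovery; lowering it makes calls more
#' conservative, and the called set is monotone in the threshold.
#'
#' @param table Cohort tibble from [combine_median()].
#' @param threshold Calling-score cutoff in (0, 1\].
#' @return `table` with a logical `called` column.
#' @export
call_junctions <- function(table, threshold = 0.15) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  table$called <- table$calling_score < threshold
  table
}

#' Per-cell read counts for a set of junctions
#'
#' Raw per-cell-barcode junctional read counts (no UMI collapse) for the
#' given junctions, in long format — a simple single-cell-resolved
#' quantification of called junctions.
#'
#' @param records Record tibble from [parse_spliced_alignments()].
#' @param junctions Tibble with `chrom`, `intron_start`, `intron_end`
#'   (e.g. the called subset of a cohort table).
#' @return Tibble (chrom, intron_start, intron_end, cell_barcode, read_count).
#' @export
count_junction_cells <- function(records, junctions) {
  key <- c("chrom", "intron_start", "intron_end")
  rec <- dplyr::semi_join(records, junctions[, key, drop = FALSE], by = key)
  rec$cell_barcode[is.na(rec$cell_barcode)] <- "none"
  rec |>
    dplyr::count(.data$chrom, .data$intron_start, .data$intron_end,
                 .data$cell_barcode, name = "read_count") |>
    dplyr::arrange(.data$chrom, .data$intron_start, .data$intron_end,
                   .data$cell_barcode)
}
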