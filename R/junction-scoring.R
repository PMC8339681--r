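#' Aggregate read scores into a junction-level score
#'
#' Combines the read-level probabilities of a junction's N reads under a
#' Bayesian two-hypothesis contrast:
#' `P = prod(p_i) / (prod(p_i) + prod(1 - p_i))`,
#' evaluated in the numerically stable log-odds form
#' `P = 1 / (1 + exp(sum log((1 - p_i)/p_i)))`. `P` is permutation-invariant
#' and strictly increasing in every `p_i`; for a single read it reduces to
#' `p_1`.
#'
#' @param p_hats Numeric vector of read scores in (0, 1).
#' @return The aggregated junction score `P` in (0, 1).
#' @export
aggregate_score <- function(p_hats) {
  if (length(p_hats) == 0L) stop("aggregate_score requires at least one read score", call. = FALSE)
  if (any(p_hats <= 0 | p_hats >= 1)) {
    stop("read scores must lie strictly inside (0, 1); clip upstream", call. = FALSE)
  }
  stats::plogis(-sum(.log_odds_against(p_hats)))
}

# per-read evidence against the junction: log((1 - p)/p)
.log_odds_against <- function(p) log1p(-p) - log(p)

#' Null distribution of the aggregated score for N-read junctions
#'
#' The aggregated score shrinks mechanically as N grows, so each observed `P`
#' is calibrated against the score of N reads drawn at random (with
#' replacement) from the sample's full read-score pool. For small N
#' (`N <= boundary`) the null is the empirical distribution of `reps`
#' resampled aggregated scores; for larger N the central limit theorem is
#' applied to the read log-odds `l_i = log((1 - p_i)/p_i)`, whose pool mean
#' and standard deviation parameterize a Gaussian null for the junction's
#' log-odds sum.
#'
#' @param sample_scores All read scores (`p_hat`) of the sample.
#' @param N Junction read count the null is built for.
#' @param reps Number of resampling replicates for the empirical null.
#' @param boundary Largest N handled by the empirical null (default 15).
#' @param seed Integer seed for the resampling draw.
#' @return An object of class `junction_null`: kind (`"empirical"` or
#'   `"gaussian"`), the null scores or (`mu`, `sigma`), `N`, `reps`, `seed`.
#' @export
build_null <- function(sample_scores, N, reps = 10000L, boundary = 15L, seed = 1L) {
  if (length(sample_scores) < 2L) {
    stop("null requires at least 2 scored reads in the sample", call. = FALSE)
  }
  stopifnot(N >= 1L, reps > 0L)
  ell <- .log_odds_against(.clip_p(sample_scores))
  if (N <= boundary) {
    null_p <- withr::with_seed(seed, {
      draws <- matrix(sample(ell, N * reps, replace = TRUE), nrow = reps)
      stats::plogis(-rowSums(draws))
    })
    structure(list(kind = "empirical", null_p = null_p, N = as.integer(N),
                   reps = as.integer(reps), boundary = as.integer(boundary),
                   seed = as.integer(seed)),
              class = "junction_null")
  } else {
    structure(list(kind = "gaussian", mu = mean(ell), sigma = stats::sd(ell),
                   N = as.integer(N), reps = as.integer(reps),
                   boundary = as.integer(boundary), seed = as.integer(seed)),
              class = "junction_null")
  }
}

#' Cumulative junction score against a resampling null
#'
#' Converts a junction's aggregated score into its position in the null:
#' the fraction of null aggregated scores below the observed `P` (ties
#' counted half) for the empirical null, or
#' `1 - pnorm((s - N*mu) / (sigma*sqrt(N)))` for the Gaussian null, where
#' `s` is the junction's observed log-odds sum (small `s` means strong
#' evidence, hence large `P` and large `P_cum`).
#'
#' @param p_hats Read scores of the junction (length must equal the null's N).
#' @param null A `junction_null` from [build_null()].
#' @return `P_cum` in \[0, 1\].
#' @export
cumulative_score <- function(p_hats, null) {
  stopifnot(inherits(null, "junction_null"))
  if (length(p_hats) != null$N) {
    stop(sprintf("null was built for N = %d but junction has %d reads",
                 null$N, length(p_hats)), call. = FALSE)
  }
  s <- sum(.log_odds_against(.clip_p(p_hats)))
  .cumulative_from_sum(s, null)
}

.cumulative_from_sum <- function(s, null) {
  if (null$kind == "empirical") {
    P <- stats::plogis(-s)
    (sum(null$null_p < P) + 0.5 * sum(null$null_p == P)) / null$reps
  } else {
    if (null$sigma == 0) {
      delta <- s - null$N * null$mu
      return(if (delta < 0) 1 else if (delta > 0) 0 else 0.5)
    }
    stats::pnorm((s - null$N * null$mu) / (null$sigma * sqrt(null$N)),
                 lower.tail = FALSE)
  }
}

#' Empirical p-value against the likely-artifact junction null
#'
#' Junctions whose reads frequently co-align contiguously elsewhere
#' (`frac_genomic >= 0.1`) are treated as likely artifacts; the distribution
#' of their cumulative scores is the null for every junction's `emp.p`:
#' `emp.p = (#\{artifact P_cum >= observed\} + 1) / (M + 1)` with M artifact
#' junctions (add-one smoothing keeps `emp.p > 0`). When fewer than
#' `min_artifact` artifact junctions exist the statistic falls back to
#' `1 - P_cum` with a warning and a fallback flag.
#'
#' @param p_cum Observed cumulative score(s); vectorized.
#' @param artifact_null Vector of artifact junctions' cumulative scores.
#' @param min_artifact Minimum artifact-null size before fallback (default 50).
#' @return List with `emp_p` (numeric, same length as `p_cum`) and
#'   `fallback` (logical scalar).
#' @export
empirical_p <- function(p_cum, artifact_null, min_artifact = 50L) {
  M <- length(artifact_null)
  if (M < min_artifact) {
    warning(sprintf(
      "artifact null has only %d junctions (< %d); falling back to emp_p = 1 - P_cum",
      M, min_artifact), call. = FALSE)
    return(list(emp_p = 1 - p_cum, fallback = TRUE))
  }
  emp <- vapply(p_cum, function(x) (sum(artifact_null >= x) + 1) / (M + 1),
                numeric(1))
  list(emp_p = emp, fallback = FALSE)
}

#' Collapse scored records into per-junction read sets
#'
#' Groups one sample's records by junction identity (chrom, intron_start,
#' intron_end) and computes the junction summaries the filters and scores
#' need: read count N, the log-odds evidence sum, the fraction of reads with
#' a genomic co-alignment, the number of distinct alignment start offsets,
#' and the mean longest homopolymer run and mean 5-mer entropy of the reads.
#'
#' @param records Record tibble from [parse_spliced_alignments()].
#' @param p_hat Read scores, row-aligned with `records`.
#' @param entropy Optional precomputed per-record entropies (recomputed from
#'   `read_seq` when omitted).
#' @return Tibble, one row per junction, sorted by (chrom, intron_start,
#'   intron_end), with the aggregated score `P`.
#' @export
collapse_to_junctions <- function(records, p_hat, entropy = NULL) {
  stopifnot(nrow(records) == length(p_hat))
  if (nrow(records) == 0L) stop("no spliced records to collapse", call. = FALSE)
  if (is.null(entropy)) entropy <- read_entropy(records$read_seq)
  df <- records
  df$p_hat <- .clip_p(p_hat)
  df$ell <- .log_odds_against(df$p_hat)
  df$entropy <- entropy
  df$run_len <- longest_base_run(df$read_seq)
  out <- df |>
    dplyr::group_by(.data$chrom, .data$intron_start, .data$intron_end) |>
    dplyr::summarise(
      strand = .consensus_strand(.data$strand),
      N = dplyr::n(),
      sum_ell = sum(.data$ell),
      frac_genomic = mean(.data$has_genomic_alignment),
      n_distinct_offsets = dplyr::n_distinct(.data$align_start),
      mean_longest_run = mean(.data$run_len),
      mean_entropy = mean(.data$entropy),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$intron_start, .data$intron_end)
  out$P <- stats::plogis(-out$sum_ell)
  out
}

.consensus_strand <- function(strand) {
  s <- unique(strand[strand %in% c("+", "-")])
  if (length(s) == 1L) s else "."
}

#' Per-sample junction filters
#'
#' Evaluates the four evidence filters a junction must pass in a sample for
#' its `emp.p` to enter the cross-sample median: genomic fraction < 0.1,
#' at least two distinct alignment start offsets (a junction supported only
#' by identically placed reads is suspect, so N = 1 junctions always fail),
#' mean longest homopolymer run < 11, and mean read entropy > 3.
#'
#' @param junctions Junction tibble from [collapse_to_junctions()].
#' @param artifact_frac Genomic-fraction threshold (default 0.1).
#' @param max_run Mean longest-run threshold (default 11).
#' @param min_entropy Mean entropy threshold (default 3).
#' @return `junctions` with logical columns `pass_genomic_fraction`,
#'   `pass_offset_diversity`, `pass_homopolymer`, `pass_entropy` and
#'   `eligible_for_median` (their conjunction).
#' @export
sample_filters <- function(junctions, artifact_frac = 0.1, max_run = 11,
                           min_entropy = 3) {
  junctions$pass_genomic_fraction <- junctions$frac_genomic < artifact_frac
  junctions$pass_offset_diversity <- junctions$n_distinct_offsets >= 2L
  junctions$pass_homopolymer <- junctions$mean_longest_run < max_run
  junctions$pass_entropy <- junctions$mean_entropy > min_entropy
  junctions$eligible_for_median <-
    junctions$pass_genomic_fraction & junctions$pass_offset_diversity &
    junctions$pass_homopolymer & junctions$pass_entropy
  junctions
}

#' Score one sample's junctions end to end
#'
#' Collapses scored records to junctions, builds one resampling null per
#' distinct read count N (empirical for `N <= null_boundary`, Gaussian
#' beyond), computes `P_cum` for every junction, forms the artifact null from
#' junctions with `frac_genomic >= artifact_frac`, assigns `emp.p` to every
#' junction, and evaluates the four per-sample filters.
#'
#' @param records Record tibble from [parse_spliced_alignments()].
#' @param p_hat Read scores, row-aligned with `records`.
#' @param sample_id Sample label for the output table.
#' @param null_reps Replicates per empirical null (default 10000).
#' @param null_boundary Largest N using the empirical null (default 15).
#' @param artifact_frac Genomic fraction defining likely-artifact junctions.
#' @param min_artifact Minimum artifact-null size before fallback.
#' @param max_run,min_entropy Filter thresholds (see [sample_filters()]).
#' @param seed Integer seed; each N's null uses a seed derived from it.
#' @param entropy Optional precomputed per-record entropies.
#' @return Per-sample junction score tibble (one row per junction) with
#'   N, P, P_cum, emp_p, summaries, filter flags, `eligible_for_median`,
#'   `null_kind` and `emp_p_fallback`.
#' @export
score_junctions <- function(records, p_hat, sample_id = records$sample_id[1],
                            null_reps = 10000L, null_boundary = 15L,
                            artifact_frac = 0.1, min_artifact = 50L,
                            max_run = 11, min_entropy = 3, seed = 1L,
                            entropy = NULL) {
  jt <- collapse_to_junctions(records, p_hat, entropy = entropy)
  pool <- .clip_p(p_hat)
  jt$P_cum <- NA_real_
  jt$null_kind <- ifelse(jt$N <= null_boundary, "empirical", "gaussian")
  for (Nv in sort(unique(jt$N))) {
    null <- build_null(pool, Nv, reps = null_reps, boundary = null_boundary,
                       seed = seed + Nv)
    rows <- which(jt$N == Nv)
    jt$P_cum[rows] <- vapply(jt$sum_ell[rows], .cumulative_from_sum,
                             numeric(1), null = null)
  }
  jt <- sample_filters(jt, artifact_frac = artifact_frac, max_run = max_run,
                       min_entropy = min_entropy)
  artifact_pool <- jt$P_cum[jt$frac_genomic >= artifact_frac]
  ep <- empirical_p(jt$P_cum, artifact_pool, min_artifact = min_artifact)
  jt$emp_p <- ep$emp_p
  jt$emp_p_fallback <- ep$fallback
  jt$sample_id <- sample_id
  dplyr::select(
    jt, "sample_id", "chrom", "intron_start", "intron_end", "strand",
    "N", "P", "P_cum", "emp_p", "frac_genomic", "n_distinct_offsets",
    "mean_longest_run", "mean_entropy", "pass_genomic_fraction",
    "pass_offset_diversity", "pass_homopolymer", "pass_entropy",
    "eligible_for_median", "null_kind", "emp_p_fallback"
  )
}
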