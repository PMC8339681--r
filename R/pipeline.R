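#' Run configuration for the junction-calling pipeline
#'
#' Bundles every tunable of the per-sample and cohort stages so a run is
#' fully described by (input files, config). All thresholds are echoed into
#' the commented header of each output TSV, making results self-describing.
#'
#' @param mode `"single"` or `"paired"`.
#' @param cap Per-class training-set cap (default 10000).
#' @param null_reps Empirical-null replicates (default 10000).
#' @param null_boundary Largest N scored with the empirical null (default 15).
#' @param artifact_frac_threshold Genomic fraction defining likely-artifact
#'   junctions (default 0.1).
#' @param min_artifact_null Minimum artifact-null size before fallback.
#' @param max_fragment_span Paired-mode mate-distance limit in bases.
#' @param homopolymer_max Filter: mean longest run must be `< 11`.
#' @param entropy_min Filter: mean read entropy must be `> 3`.
#' @param calling_threshold Cohort calling-score cutoff (default 0.15).
#' @param seed Integer seed driving every stochastic step.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("single", "paired"), cap = 10000L,
                       null_reps = 10000L, null_boundary = 15L,
                       artifact_frac_threshold = 0.1, min_artifact_null = 50L,
                       max_fragment_span = 1e6, homopolymer_max = 11,
                       entropy_min = 3, calling_threshold = 0.15, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(
    mode = mode, cap = as.integer(cap), null_reps = as.integer(null_reps),
    null_boundary = as.integer(null_boundary),
    artifact_frac_threshold = artifact_frac_threshold,
    min_artifact_null = as.integer(min_artifact_null),
    max_fragment_span = max_fragment_span,
    homopolymer_max = homopolymer_max, entropy_min = entropy_min,
    calling_threshold = calling_threshold, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

.config_header <- function(config, sample_id = NULL) {
  kv <- vapply(names(unclass(config)), function(k)
    sprintf("# %s=%s", k, format(config[[k]], scientific = FALSE)), character(1))
  c(sprintf("# sjcall %s", as.character(utils::packageVersion("sjcall"))),
    if (!is.null(sample_id)) sprintf("# sample_id=%s", sample_id),
    kv)
}

.write_table_with_header <- function(df, path, header) {
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by the pipeline (commented header skipped)
#'
#' @param path File path.
#' @param required Column names that must be present (schema check).
#' @return A tibble.
#' @export
read_pipeline_table <- function(path, required = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(sprintf("%s: schema mismatch, missing column(s) %s",
                   path, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Score one sample end to end
#'
#' Runs the full per-sample stage on one alignment file: parse spliced
#' alignments, extract features, build the training set from genomic
#' co-alignment status, fit the penalized logistic read model, score every
#' junctional read, and score and filter the sample's junctions. Writes the
#' per-read feature table, the serialized model and the junction score table
#' into `out_dir`, each with a commented header echoing the configuration.
#'
#' @param path Alignment file (SAM/BAM); two files (R1, R2) in paired mode.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param sample_id Sample label; defaults to the first file's basename.
#' @return List with `junctions` (tibble), `model`, `features`, `records`
#'   and the output `paths`.
#' @export
run_sample <- function(path, out_dir, config = run_config(),
                       sample_id = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  parsed <- parse_spliced_alignments(path, mode = config$mode,
                                     sample_id = sample_id)
  sample_id <- parsed$sample_id
  feats <- extract_features(parsed, max_fragment_span = config$max_fragment_span)
  training <- build_training_set(feats, parsed$records$has_genomic_alignment,
                                 cap = config$cap, seed = config$seed)
  message(sprintf("[%s] training classes: %d positive / %d negative junctional reads",
                  sample_id, training$n_pos, training$n_neg))
  model <- fit_read_model(training, mode = config$mode, seed = config$seed)
  p_hat <- score_reads(model, feats)
  junctions <- score_junctions(
    parsed$records, p_hat, sample_id = sample_id,
    null_reps = config$null_reps, null_boundary = config$null_boundary,
    artifact_frac = config$artifact_frac_threshold,
    min_artifact = config$min_artifact_null,
    max_run = config$homopolymer_max, min_entropy = config$entropy_min,
    seed = config$seed, entropy = feats$entropy)
  message(sprintf(
    "[%s] %d junctions (%d empirical-null, %d gaussian-null), artifact null M=%d",
    sample_id, nrow(junctions), sum(junctions$null_kind == "empirical"),
    sum(junctions$null_kind == "gaussian"),
    sum(junctions$frac_genomic >= config$artifact_frac_threshold)))

  header <- .config_header(config, sample_id)
  feature_table <- dplyr::bind_cols(
    parsed$records[, c("read_id", "sample_id", "cell_barcode", "chrom",
                       "intron_start", "intron_end", "strand", "nh", "hi",
                       "nmm", "as_raw")],
    feats[, setdiff(names(feats), c("read_id", "nh", "nmm"))],
    parsed$records[, c("has_genomic_alignment", "align_start_offset")])
  paths <- list(
    junctions = file.path(out_dir, paste0(sample_id, ".junctions.tsv")),
    features = file.path(out_dir, paste0(sample_id, ".features.tsv")),
    model = file.path(out_dir, paste0(sample_id, ".model.txt")))
  .write_table_with_header(junctions, paths$junctions, header)
  .write_table_with_header(feature_table, paths$features, header)
  write_read_model(model, paths$model)
  list(junctions = junctions, model = model, features = feats,
       records = parsed$records, paths = paths)
}

#' Combine per-sample junction tables and call junctions
#'
#' Cohort stage: reads the per-sample junction TSVs (schema-checked),
#' computes each junction's calling score (median empirical p-value over
#' filter-passing samples) and applies the calling threshold. Every junction
#' receives the same call decision wherever it is reported.
#'
#' @param sample_paths Per-sample junction TSV paths from [run_sample()]
#'   (alternatively a list of junction tibbles).
#' @param out Output TSV path (optional).
#' @param config A [run_config()]; `calling_threshold` is used.
#' @return The called cohort tibble.
#' @export
run_cohort <- function(sample_paths, out = NULL, config = run_config()) {
  required <- c("sample_id", "chrom", "intron_start", "intron_end", "strand",
                "N", "emp_p", "eligible_for_median")
  tables <- if (is.character(sample_paths)) {
    lapply(sample_paths, read_pipeline_table, required = required)
  } else sample_paths
  cohort <- call_junctions(combine_median(tables),
                           threshold = config$calling_threshold)
  if (!is.null(out)) {
    .write_table_with_header(cohort, out, .config_header(config))
  }
  cohort
}
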