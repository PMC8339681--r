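#' Configuration for the synthetic spliced-alignment simulator
#'
#' Defines a cohort of samples sharing one set of splice junctions with known
#' truth labels. True junctions emulate expressed splice sites: reads with
#' high-complexity sequence, unique mapping (NH mostly 1), few mismatches and
#' diverse overhangs, and only rarely a contiguous co-alignment. Artifact
#' junctions emulate the noise the caller must reject — repetitive
#' (low-entropy) sequence from PCR stutter and template switching that
#' multimaps (high NH), carries more mismatches and soft-clipping, and
#' usually also aligns contiguously to a genomic decoy position. True
#' junctions receive more reads than artifacts, as expressed genes accumulate
#' junctional coverage while artifact loci stay shallow.
#'
#' @param n_true_junctions,n_artifact_junctions Junctions per class.
#' @param reads_per_junction List: `dist` (`"poisson"` or `"fixed"`), per-class
#'   `true`/`artifact` mean (or fixed count), and `min` count floor.
#' @param read_length Read length in bases (default 60).
#' @param entropy_regime List with `artifact_units`, the short repeat units
#'   artifact-class reads are built from (true-class reads are uniform random
#'   nucleotides).
#' @param p_genomic_coalignment Named numeric `c(true=, artifact=)`:
#'   per-read probability of an additional N-free alignment line.
#' @param nh_spec NH draw: `true_values`/`true_probs` and `artifact_values`
#'   (uniform).
#' @param mismatch_lambda Named Poisson means for the per-read mismatch count.
#' @param softclip_prob Named per-class probability a read is soft-clipped
#'   (length uniform on 1..`softclip_max`).
#' @param softclip_max Maximum soft-clip length.
#' @param min_overhang Minimum aligned bases on each side of a junction.
#' @param n_background_reads Contiguous (non-junctional) reads per sample.
#' @param n_samples Samples in the cohort.
#' @param n_cells Synthetic cell barcodes per sample.
#' @param seed Integer seed; the junction layout depends only on `seed`, the
#'   reads on (`seed`, sample index), so generation is a pure function of the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_true_junctions = 50L, n_artifact_junctions = 50L,
                       reads_per_junction = list(dist = "poisson", true = 24,
                                                 artifact = 10, min = 2L),
                       read_length = 60L,
                       entropy_regime = list(artifact_units = c("AC", "TC", "AG", "CA")),
                       p_genomic_coalignment = c(true = 0.02, artifact = 0.8),
                       nh_spec = list(true_values = c(1L, 2L),
                                      true_probs = c(0.9, 0.1),
                                      artifact_values = 2:12),
                       mismatch_lambda = c(true = 0.3, artifact = 2),
                       softclip_prob = c(true = 0.2, artifact = 0.4),
                       softclip_max = 8L,
                       min_overhang = 10L,
                       n_background_reads = 20L,
                       n_samples = 2L,
                       n_cells = 24L,
                       seed = 1L) {
  cfg <- list(
    n_true_junctions = as.integer(n_true_junctions),
    n_artifact_junctions = as.integer(n_artifact_junctions),
    reads_per_junction = reads_per_junction,
    read_length = as.integer(read_length),
    entropy_regime = entropy_regime,
    p_genomic_coalignment = p_genomic_coalignment,
    nh_spec = nh_spec,
    mismatch_lambda = mismatch_lambda,
    softclip_prob = softclip_prob,
    softclip_max = as.integer(softclip_max),
    min_overhang = as.integer(min_overhang),
    n_background_reads = as.integer(n_background_reads),
    n_samples = as.integer(n_samples),
    n_cells = as.integer(n_cells),
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_true_junctions >= 0L, cfg$n_artifact_junctions >= 0L,
            cfg$read_length >= 20L,
            all(cfg$p_genomic_coalignment >= 0 & cfg$p_genomic_coalignment <= 1),
            all(cfg$softclip_prob >= 0 & cfg$softclip_prob <= 1))
  if (2L * cfg$min_overhang + cfg$softclip_max > cfg$read_length) {
    stop("read_length too short for the requested overhangs: would produce overhang < 1",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Junction layout shared by all samples of the cohort; depends only on
# config$seed. One synthetic chromosome; classes interleaved at random.
.junction_layout <- function(config) {
  ntot <- config$n_true_junctions + config$n_artifact_junctions
  withr::with_seed(config$seed, {
    starts <- sort(sample(seq(10000L, 1890000L, by = 1000L), ntot)) +
      sample(0:999, ntot, replace = TRUE)
    ilen <- sample(80:5000, ntot, replace = TRUE)
    cls <- sample(c(rep("true", config$n_true_junctions),
                    rep("artifact", config$n_artifact_junctions)))
    decoy <- sample(seq(10000L, 1890000L), ntot, replace = TRUE)
  })
  tibble::tibble(
    junction_id = sprintf("J%04d", seq_len(ntot)),
    chrom = "chrS1",
    intron_start = as.integer(starts),
    intron_end = as.integer(starts + ilen - 1L),
    class = cls,
    decoy_pos = as.integer(decoy)
  )
}

.random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

.repeat_seq <- function(unit, n) {
  substr(strrep(unit, ceiling(n / nchar(unit))), 1L, n)
}

.mutate_seq <- function(seq, nmm) {
  if (nmm == 0L) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(s), min(nmm, length(s)))
  s[pos] <- vapply(s[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
  paste(s, collapse = "")
}

#' Simulate one sample's SAM file with known junction truth
#'
#' Emits a header-complete SAM file of junctional alignments for every
#' junction in the cohort layout (plus contiguous background reads). Each
#' junctional read carries NH, HI, AS, NM and CB tags and an N-bearing CIGAR
#' consistent with its overhangs; AS is generated as
#' `read_length - 2*nmm - softclip`. Reads drawn for genomic co-alignment get
#' an additional N-free secondary line at the junction's decoy position.
#' Generation is deterministic: the same (config, sample_index) yields a
#' byte-identical file.
#'
#' @param config A [sim_config()].
#' @param sample_index 1-based sample number within the cohort.
#' @param dir Output directory (created if needed).
#' @return List with `sam` (file path), `junctions` (junction truth tibble)
#'   and `reads` (per-read truth tibble).
#' @export
simulate_sample <- function(config, sample_index = 1L, dir = tempdir()) {
  stopifnot(inherits(config, "sim_config"))
  layout <- .junction_layout(config)
  L <- config$read_length
  rpj <- config$reads_per_junction
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  sam_buf <- list()
  read_rows <- list()
  emit <- function(line) sam_buf[[length(sam_buf) + 1L]] <<- line
  withr::with_seed(config$seed + 7919L * as.integer(sample_index), {
    barcodes <- unique(vapply(seq_len(config$n_cells), function(i) .random_seq(8L),
                              character(1)))
    for (j in seq_len(nrow(layout))) {
      cls <- layout$class[j]
      n_reads <- switch(rpj$dist,
        fixed = as.integer(rpj[[cls]]),
        poisson = max(rpj$min, stats::rpois(1, rpj[[cls]])),
        stop(sprintf("unknown reads_per_junction dist: %s", rpj$dist), call. = FALSE))
      for (r in seq_len(n_reads)) {
        qname <- sprintf("s%d_%s_r%04d", sample_index, layout$junction_id[j], r)
        nmm <- stats::rpois(1, config$mismatch_lambda[[cls]])
        sc <- if (stats::runif(1) < config$softclip_prob[[cls]]) {
          sample(config$softclip_max, 1)
        } else 0L
        aligned <- L - sc
        left <- sample(config$min_overhang:(aligned - config$min_overhang), 1)
        right <- aligned - left
        cigar <- paste0(if (sc > 0) sprintf("%dS", sc) else "",
                        left, "M",
                        layout$intron_end[j] - layout$intron_start[j] + 1L, "N",
                        right, "M")
        pos <- layout$intron_start[j] - left
        nh <- if (cls == "true") {
          sample(config$nh_spec$true_values, 1, prob = config$nh_spec$true_probs)
        } else sample(config$nh_spec$artifact_values, 1)
        seq <- if (cls == "true") {
          .random_seq(L)
        } else {
          unit <- sample(config$entropy_regime$artifact_units, 1)
          .repeat_seq(unit, L)
        }
        seq <- .mutate_seq(seq, nmm)
        as_tag <- L - 2L * nmm - sc
        cb <- sample(barcodes, 1)
        qual <- strrep("I", L)
        emit(paste(
          qname, "0", "chrS1", pos, "255", cigar, "*", "0", "0", seq, qual,
          sprintf("NH:i:%d", nh), "HI:i:1", sprintf("AS:i:%d", as_tag),
          sprintf("NM:i:%d", nmm), sprintf("CB:Z:%s", cb), sep = "\t"))
        co_aligned <- stats::runif(1) < config$p_genomic_coalignment[[cls]]
        if (co_aligned) {
          emit(paste(
            qname, "256", "chrS1", layout$decoy_pos[j], "0", sprintf("%dM", L),
            "*", "0", "0", seq, qual,
            sprintf("NH:i:%d", max(nh, 2L)), "HI:i:2",
            sprintf("AS:i:%d", L - 2L * nmm), sprintf("NM:i:%d", nmm),
            sprintf("CB:Z:%s", cb), sep = "\t"))
        }
        read_rows[[length(read_rows) + 1L]] <- tibble::tibble(
          read_id = qname, chrom = "chrS1",
          intron_start = layout$intron_start[j],
          intron_end = layout$intron_end[j],
          class = cls, nmm = nmm, nh = nh, softclip = sc,
          left_overhang = left, right_overhang = right,
          has_genomic_coalignment = co_aligned)
      }
    }
    for (b in seq_len(config$n_background_reads)) {
      qname <- sprintf("s%d_bg_r%04d", sample_index, b)
      pos <- sample(seq(10000L, 1890000L), 1)
      seq <- .random_seq(L)
      emit(paste(
        qname, "0", "chrS1", pos, "255", sprintf("%dM", L), "*", "0", "0",
        seq, strrep("I", L), "NH:i:1", "HI:i:1", sprintf("AS:i:%d", L),
        "NM:i:0", sprintf("CB:Z:%s", sample(barcodes, 1)), sep = "\t"))
    }
  })
  header <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chrS1\tLN:2000000")
  path <- file.path(dir, sprintf("sample_%d.sam", sample_index))
  writeLines(c(header, unlist(sam_buf)), path)
  list(sam = path,
       junctions = layout[, c("junction_id", "chrom", "intron_start",
                              "intron_end", "class")],
       reads = dplyr::bind_rows(read_rows))
}

#' Simulate a cohort of samples sharing one junction truth
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return List with `sams` (paths, one per sample), `junctions` (shared
#'   junction truth) and `reads` (list of per-sample read-truth tibbles).
#' @export
simulate_cohort <- function(config, dir = tempdir()) {
  sims <- lapply(seq_len(config$n_samples), function(i)
    simulate_sample(config, i, dir))
  list(sams = vapply(sims, `[[`, character(1), "sam"),
       junctions = sims[[1]]$junctions,
       reads = lapply(sims, `[[`, "reads"))
}

#' Evaluate cohort calls against simulation truth
#'
#' Joins a called cohort table to the junction truth and reports the
#' confusion counts at the calling threshold plus a threshold-free ranking
#' statistic: the probability that a random true junction has a lower
#' calling score than a random artifact junction (ties counted half),
#' computed exactly over all pairs from the rank-sum.
#'
#' @param cohort Cohort tibble from [call_junctions()] (needs `called`).
#' @param truth Junction truth tibble (`chrom`, `intron_start`, `intron_end`,
#'   `class`).
#' @return List with `confusion` (tp, fp, tn, fn) and `ranking` (the pairwise
#'   ranking statistic).
#' @export
evaluate_calls <- function(cohort, truth) {
  key <- c("chrom", "intron_start", "intron_end")
  merged <- dplyr::inner_join(cohort, truth, by = key)
  orphans_cohort <- nrow(cohort) - nrow(merged)
  orphans_truth <- nrow(truth) - nrow(merged)
  if (orphans_cohort > 0L || orphans_truth > 0L) {
    miss <- dplyr::anti_join(truth, cohort, by = key)
    extra <- dplyr::anti_join(cohort, truth, by = key)
    stop(sprintf(
      "junction key mismatch: %d truth junction(s) absent from cohort (e.g. %s); %d unexplained cohort junction(s)",
      nrow(miss),
      if (nrow(miss)) paste0(miss$chrom[1], ":", miss$intron_start[1], "-", miss$intron_end[1]) else "-",
      nrow(extra)), call. = FALSE)
  }
  is_true <- merged$class == "true"
  confusion <- c(tp = sum(merged$called & is_true),
                 fp = sum(merged$called & !is_true),
                 tn = sum(!merged$called & !is_true),
                 fn = sum(!merged$called & is_true))
  n_t <- sum(is_true); n_a <- sum(!is_true)
  ranking <- if (n_t > 0L && n_a > 0L) {
    r <- rank(merged$calling_score, ties.method = "average")
    (sum(r[!is_true]) - n_a * (n_a + 1) / 2) / (n_t * n_a)
  } else NA_real_
  list(confusion = confusion, ranking = ranking)
}
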