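#' Overlapping k-mer profile of a nucleotide sequence
#'
#' Enumerates all overlapping k-mers of `seq` from left to right and tabulates
#' their occurrence counts. The profile underlies the read-entropy statistic
#' used as a model predictor and as a junction-level filter: repetitive
#' sequences (PCR stutter, low-complexity genomic regions) have few distinct
#' k-mers and correspondingly low entropy.
#'
#' @param seq A single nucleotide string of length >= `k`.
#' @param k k-mer width in bases (default 5).
#' @return An object of class `kmer_profile`: a list with `k`, `counts`
#'   (named integer vector, k-mer -> occurrence count, in order of first
#'   appearance), `n_positions` (number of overlapping k-mers, `L - k + 1`)
#'   and `n_unique` (number of distinct k-mers).
#' @examples
#' kp <- kmer_profile("ACTCCGAGTCCTCCG")
#' kp$counts[["CTCCG"]]  # 2
#' @export
kmer_profile <- function(seq, k = 5L) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer", call. = FALSE)
  L <- nchar(seq)
  if (L < k) {
    stop(sprintf("sequence of length %d is shorter than the minimum length k = %d",
                 L, k), call. = FALSE)
  }
  n_pos <- L - k + 1L
  kmers <- substring(seq, seq_len(n_pos), seq_len(n_pos) + k - 1L)
  counts <- table(factor(kmers, levels = unique(kmers)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(k = k, counts = counts, n_positions = n_pos,
         n_unique = length(counts)),
    class = "kmer_profile"
  )
}

#' Shannon entropy of a read's overlapping k-mer composition
#'
#' Computes `-sum f_i * log(f_i)` over the distinct k-mers of the sequence,
#' with `f_i` the frequency of k-mer i among all `L - k + 1` overlapping
#' k-mers and natural logarithm (result in nats). The entropy is 0 for a
#' perfectly repetitive sequence (a single distinct k-mer) and attains its
#' maximum `log(L - k + 1)` when all k-mers are distinct.
#'
#' @param seq A single nucleotide string of length >= `k`, or a character
#'   vector (the entropy is computed element-wise).
#' @param k k-mer width in bases (default 5).
#' @return Numeric vector of entropies in nats, one per input sequence.
#' @examples
#' read_entropy("AAAAAAAAAA")  # 0: one distinct 5-mer
#' @export
read_entropy <- function(seq, k = 5L) {
  vapply(seq, function(s) {
    kp <- kmer_profile(s, k)
    f <- kp$counts / kp$n_positions
    -sum(f * log(f))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Longest single-base run in a sequence
#'
#' Length of the longest maximal stretch of one repeated base (A, C, G or T).
#' The mean longest run over a junction's reads is one of the per-sample
#' junction filters: long homopolymers are a signature of artifactual
#' alignments.
#'
#' @param seq A non-empty nucleotide string, or a character vector
#'   (computed element-wise).
#' @return Integer vector of run lengths.
#' @examples
#' longest_base_run("AAATTC")  # 3
#' @export
longest_base_run <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || !nzchar(s)) {
      stop("longest_base_run requires a non-empty sequence", call. = FALSE)
    }
    max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}
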