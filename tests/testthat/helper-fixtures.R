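# Builders for small in-memory SAM fixtures and record tables.

write_sam <- function(lines, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:chr1\tLN:1000000",
               "@SQ\tSN:chr2\tLN:1000000",
               lines), path)
  path
}

aln_line <- function(qname, pos, cigar, seq, flag = 0, chrom = "chr1",
                     nh = 1, hi = 1, as_tag = NULL, nm = 0,
                     extra = character()) {
  L <- nchar(seq)
  if (is.null(as_tag)) as_tag <- L
  paste(c(qname, flag, chrom, pos, "255", cigar, "*", "0", "0", seq,
          strrep("I", L),
          sprintf("NH:i:%d", nh), sprintf("HI:i:%d", hi),
          sprintf("AS:i:%d", as_tag), sprintf("NM:i:%d", nm), extra),
        collapse = "\t")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Minimal record tibble for junction-level operations (no SAM round trip).
make_records <- function(n, chrom = "chr1", intron_start = 500L,
                         intron_end = 700L, align_start = NULL,
                         seqs = NULL, genomic = FALSE,
                         sample_id = "s1") {
  if (is.null(align_start)) align_start <- intron_start - (20L + seq_len(n))
  if (is.null(seqs)) seqs <- vapply(seq_len(n), function(i) rand_seq(60L), "")
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)),
    sample_id = sample_id,
    chrom = chrom,
    intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end),
    strand = ".",
    align_start = as.integer(align_start),
    read_seq = seqs,
    has_genomic_alignment = rep_len(genomic, n)
  )
}
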