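#' @importFrom rlang .data
NULL

# Read one SAM or BAM file into a flat tibble of mapped, non-supplementary
# alignment lines with the tags the model needs. SAM input is converted with
# Rsamtools::asBam into a temporary file first.
.read_alignment_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("alignment file not found: %s", path), call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq"),
    tag = c("NH", "HI", "AS", "NM", "XS", "CB", "UB", "CR", "UR"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(ga)
  tag_or_na <- function(name, n) {
    if (name %in% colnames(mc)) mc[[name]] else rep(NA, n)
  }
  n <- length(ga)
  seqs <- as.character(mc$seq)
  seqs[!nzchar(seqs)] <- NA_character_
  tibble::tibble(
    qname = mc$qname,
    flag = mc$flag,
    chrom = as.character(GenomeInfoDb::seqnames(ga)),
    pos = BiocGenerics::start(ga),
    is_reverse = as.character(BiocGenerics::strand(ga)) == "-",
    cigar = GenomicAlignments::cigar(ga),
    seq = seqs,
    nh = as.integer(tag_or_na("NH", n)),
    hi = as.integer(tag_or_na("HI", n)),
    as_raw = as.integer(tag_or_na("AS", n)),
    nmm = as.integer(tag_or_na("NM", n)),
    xs = as.character(tag_or_na("XS", n)),
    cb = as.character(tag_or_na("CB", n)),
    ub = as.character(tag_or_na("UB", n))
  )
}

# Mate label for each alignment line: FLAG bits 0x40/0x80 when set, else the
# label the caller assigned to the whole file ("R1"/"R2"), else "unpaired".
.mate_label <- function(flag, file_label) {
  lab <- rep(file_label, length(flag))
  lab[bitwAnd(flag, 64L) > 0L] <- "R1"
  lab[bitwAnd(flag, 128L) > 0L] <- "R2"
  lab
}

#' Parse spliced alignments from SAM/BAM into junction-level read records
#'
#' Extracts every non-chimeric spliced alignment (a mapped line whose CIGAR
#' contains an N operator) from one sample's alignment file(s) and explodes it
#' into one record per N operator, each annotated with the splice junction it
#' spans (1-based first and last intronic base, STAR `SJ.out.tab` convention).
#' When a read has several spliced alignments, only the one with the lowest HI
#' tag is retained so that a multimapping read is counted once. All reads with
#' at least one contiguous (N-free) alignment anywhere in the input form the
#' "genomic" set; junctional reads in that set are the likely-artifact class
#' used to train the read model.
#'
#' Supplementary (chimeric) alignment lines are ignored entirely; secondary
#' lines count toward the genomic set and HI selection. The tags NH, HI, AS
#' and NM are required on every spliced line.
#'
#' @param path Path to a SAM or BAM file; in paired mode optionally a vector
#'   of two paths (R1 then R2) when mates were aligned separately.
#' @param mode `"single"` or `"paired"`. Paired mode identifies mates by the
#'   FLAG first/second-in-pair bits (or by file of origin) and collects the
#'   mate summaries needed for the paired feature set.
#' @param sample_id Sample label carried into every record; defaults to the
#'   first file's basename without extension.
#' @return An object of class `spliced_alignments`: a list with
#'   * `records`: tibble, one row per retained spliced record per junction
#'     (read id, junction coordinates, CIGAR-derived overhangs, tags,
#'     sequence, `has_genomic_alignment`, ...);
#'   * `genomic_ids`: character vector of read units with an N-free alignment;
#'   * `mates`: in paired mode, a per-read-unit summary tibble used by
#'     [extract_features()]; `NULL` otherwise;
#'   * `mode`, `sample_id`.
#' @export
parse_spliced_alignments <- function(path, mode = c("single", "paired"),
                                     sample_id = NULL) {
  mode <- match.arg(mode)
  if (mode == "single" && length(path) != 1L) {
    stop("single mode takes exactly one alignment file", call. = FALSE)
  }
  if (!length(path) %in% c(1L, 2L)) {
    stop("supply one alignment file, or two (R1, R2) in paired mode", call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(path[1]), ignore.case = TRUE)
  }
  file_labels <- if (mode == "paired" && length(path) == 2L) c("R1", "R2") else "unpaired"
  aln <- dplyr::bind_rows(lapply(seq_along(path), function(i) {
    df <- .read_alignment_file(path[i])
    df$mate <- .mate_label(df$flag, if (length(path) == 2L) file_labels[i] else "unpaired")
    df
  }))
  if (mode == "single") aln$mate <- "unpaired"
  aln$unit <- if (mode == "paired") paste(aln$qname, aln$mate, sep = "/") else aln$qname

  spliced <- grepl("N", aln$cigar, fixed = TRUE)
  genomic_ids <- sort(unique(aln$unit[!spliced]))

  sp <- aln[spliced, , drop = FALSE]
  if (nrow(sp) == 0L) {
    return(structure(list(records = .empty_records(), genomic_ids = genomic_ids,
                          mates = NULL, mode = mode, sample_id = sample_id),
                     class = "spliced_alignments"))
  }
  for (tag in c("nh", "hi", "as_raw", "nmm")) {
    bad <- which(is.na(sp[[tag]]))
    if (length(bad)) {
      tag_name <- c(nh = "NH", hi = "HI", as_raw = "AS", nmm = "NM")[[tag]]
      stop(sprintf("read %s: missing required tag %s", sp$qname[bad[1]], tag_name),
           call. = FALSE)
    }
  }
  # lowest-HI spliced alignment per read unit
  keep <- unlist(lapply(split(seq_len(nrow(sp)), sp$unit), function(ix) {
    ix[which.min(sp$hi[ix])]
  }), use.names = FALSE)
  sp <- sp[sort(keep), , drop = FALSE]

  records <- .explode_junction_records(sp, sample_id)
  records$has_genomic_alignment <- records$unit %in% genomic_ids

  mates <- NULL
  if (mode == "paired") {
    mates <- .mate_summaries(aln, sp, records)
  }
  structure(list(records = records, genomic_ids = genomic_ids, mates = mates,
                 mode = mode, sample_id = sample_id),
            class = "spliced_alignments")
}

.empty_records <- function() {
  tibble::tibble(
    read_id = character(), unit = character(), sample_id = character(),
    cell_barcode = character(), umi = character(), mate = character(),
    chrom = character(), intron_start = integer(), intron_end = integer(),
    strand = character(), cigar = character(), align_start = integer(),
    hi = integer(), nh = integer(), nmm = integer(), as_raw = integer(),
    read_length = integer(), read_seq = character(), is_reverse = logical(),
    left_overhang = integer(), right_overhang = integer(),
    softclip_s = integer(), align_start_offset = integer(),
    has_genomic_alignment = logical()
  )
}

# One record per N operator of each retained spliced alignment, with the
# junction's intron coordinates and the aligned-block (M/=/X) overhang on
# either side of that N (adjacent Ns bound the block).
.explode_junction_records <- function(sp, sample_id) {
  ops <- GenomicAlignments::explodeCigarOps(sp$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(sp$cigar)
  introns <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    sp$cigar, pos = sp$pos, ops = "N")
  op_tab <- GenomicAlignments::cigarOpTable(sp$cigar)
  read_len <- as.integer(rowSums(op_tab[, c("M", "I", "S", "=", "X"), drop = FALSE]))
  softclip <- as.integer(op_tab[, "S"])
  no_seq <- is.na(sp$seq)
  if (any(no_seq)) {
    stop(sprintf("read %s: retained spliced alignment has no SEQ",
                 sp$qname[which(no_seq)[1]]), call. = FALSE)
  }
  bad_len <- which(nchar(sp$seq) != read_len)
  if (length(bad_len)) {
    i <- bad_len[1]
    stop(sprintf("read %s: CIGAR %s implies %d read bases but SEQ has %d",
                 sp$qname[i], sp$cigar[i], read_len[i], nchar(sp$seq[i])),
         call. = FALSE)
  }
  # aligned bases per inter-N segment, one numeric vector per alignment
  seg_sums <- lapply(seq_len(nrow(sp)), function(i) {
    op <- ops[[i]]; ln <- lens[[i]]
    seg <- cumsum(op == "N") - (op == "N") + 1L
    unname(vapply(split(ln * (op %in% c("M", "=", "X")), seg), sum, numeric(1)))
  })
  nj <- lengths(seg_sums) - 1L
  idx <- rep.int(seq_len(nrow(sp)), nj)
  ir <- unlist(introns, use.names = FALSE)
  rec <- tibble::tibble(
    read_id = sp$qname[idx],
    unit = sp$unit[idx],
    sample_id = sample_id,
    cell_barcode = sp$cb[idx],
    umi = sp$ub[idx],
    mate = sp$mate[idx],
    chrom = sp$chrom[idx],
    intron_start = BiocGenerics::start(ir),
    intron_end = BiocGenerics::end(ir),
    strand = ifelse(is.na(sp$xs[idx]), ".", sp$xs[idx]),
    cigar = sp$cigar[idx],
    align_start = sp$pos[idx],
    hi = sp$hi[idx], nh = sp$nh[idx], nmm = sp$nmm[idx], as_raw = sp$as_raw[idx],
    read_length = read_len[idx],
    read_seq = sp$seq[idx],
    is_reverse = sp$is_reverse[idx],
    left_overhang = as.integer(unlist(lapply(seg_sums, function(v) v[-length(v)]),
                                      use.names = FALSE)),
    right_overhang = as.integer(unlist(lapply(seg_sums, function(v) v[-1]),
                                       use.names = FALSE)),
    softclip_s = softclip[idx]
  )
  rec$align_start_offset <- rec$intron_start - rec$align_start
  rec
}

# Per-read-unit mate summary for paired mode: the unit's retained spliced
# alignment when it has one (first junction's overhangs), else its primary
# contiguous alignment. Used to fill the mate half of the paired feature set.
.mate_summaries <- function(aln, sp_retained, records) {
  first_rec <- records[!duplicated(records$unit), , drop = FALSE]
  spliced_sum <- tibble::tibble(
    unit = first_rec$unit,
    chrom = first_rec$chrom, pos = first_rec$align_start,
    is_reverse = first_rec$is_reverse,
    nh = first_rec$nh, nmm = first_rec$nmm, as_raw = first_rec$as_raw,
    read_length = first_rec$read_length,
    overlap = pmin(first_rec$left_overhang, first_rec$right_overhang),
    max_overlap = pmax(first_rec$left_overhang, first_rec$right_overhang),
    softclip_s = first_rec$softclip_s,
    entropy = read_entropy(first_rec$read_seq)
  )
  contig <- aln[!grepl("N", aln$cigar, fixed = TRUE), , drop = FALSE]
  contig <- contig[bitwAnd(contig$flag, 256L) == 0L, , drop = FALSE]
  contig <- contig[!duplicated(contig$unit), , drop = FALSE]
  contig <- contig[!contig$unit %in% spliced_sum$unit, , drop = FALSE]
  contig_sum <- tibble::tibble(
    unit = contig$unit,
    chrom = contig$chrom, pos = contig$pos, is_reverse = contig$is_reverse,
    nh = contig$nh, nmm = contig$nmm, as_raw = contig$as_raw,
    read_length = GenomicAlignments::cigarWidthAlongQuerySpace(contig$cigar),
    overlap = 0L, max_overlap = 0L,
    softclip_s = vapply(seq_len(nrow(contig)), function(i) {
      op <- GenomicAlignments::explodeCigarOps(contig$cigar[i])[[1]]
      ln <- GenomicAlignments::explodeCigarOpLengths(contig$cigar[i])[[1]]
      as.integer(sum(ln[op == "S"]))
    }, integer(1)),
    entropy = ifelse(is.na(contig$seq), 0, read_entropy(ifelse(is.na(contig$seq), "AAAAA", contig$seq)))
  )
  dplyr::bind_rows(spliced_sum, contig_sum)
}

.other_mate <- function(mate) ifelse(mate == "R1", "R2", "R1")

#' Per-read model features for spliced alignment records
#'
#' Computes the predictor set of the read-level model from parsed records:
#' the length-normalized alignment score (`as_norm = AS / read_length`),
#' multimapping count NH, mismatch count nmm, the shorter and longer aligned
#' overhang flanking the record's junction (`overlap`, `max_overlap`), total
#' soft-clipped bases, and the 5-mer sequence entropy. In paired mode the
#' same seven features of the mate are appended (zeros when the mate is
#' missing) together with two fragment-compatibility indicators:
#' `strand_compatible` (R1 forward and R2 reverse on the same reference) and
#' `location_compatible` (additionally, leftmost positions within
#' `max_fragment_span`).
#'
#' @param x A `spliced_alignments` object from [parse_spliced_alignments()].
#' @param max_fragment_span Maximum distance in bases between mate leftmost
#'   positions still considered compatible with one cDNA fragment.
#' @return A tibble with one row per record, row-aligned with `x$records`.
#' @export
extract_features <- function(x, max_fragment_span = 1e6) {
  stopifnot(inherits(x, "spliced_alignments"))
  rec <- x$records
  f <- tibble::tibble(
    read_id = rec$read_id,
    as_norm = rec$as_raw / rec$read_length,
    nh = as.numeric(rec$nh),
    nmm = as.numeric(rec$nmm),
    overlap = pmin(rec$left_overhang, rec$right_overhang),
    max_overlap = pmax(rec$left_overhang, rec$right_overhang),
    softclip_s = as.numeric(rec$softclip_s),
    entropy = if (nrow(rec)) read_entropy(rec$read_seq) else numeric()
  )
  if (nrow(rec) && any(f$overlap <= 0)) {
    stop("junction record with non-positive overhang: malformed CIGAR", call. = FALSE)
  }
  if (x$mode == "paired") {
    mate_unit <- paste(rec$read_id, .other_mate(rec$mate), sep = "/")
    m <- x$mates[match(mate_unit, x$mates$unit), , drop = FALSE]
    present <- !is.na(m$unit)
    zero <- function(v) ifelse(present, v, 0)
    f$mate_as_norm <- zero(m$as_raw / m$read_length)
    f$mate_nh <- zero(as.numeric(m$nh))
    f$mate_nmm <- zero(as.numeric(m$nmm))
    f$mate_overlap <- zero(as.numeric(m$overlap))
    f$mate_max_overlap <- zero(as.numeric(m$max_overlap))
    f$mate_softclip_s <- zero(as.numeric(m$softclip_s))
    f$mate_entropy <- zero(m$entropy)
    r1_rev <- ifelse(rec$mate == "R1", rec$is_reverse, m$is_reverse)
    r2_rev <- ifelse(rec$mate == "R2", rec$is_reverse, m$is_reverse)
    same_ref <- rec$chrom == m$chrom
    strand_ok <- present & same_ref & !r1_rev & r2_rev
    f$strand_compatible <- as.numeric(strand_ok %in% TRUE)
    gap_ok <- abs(rec$align_start - m$pos) <= max_fragment_span
    f$location_compatible <- as.numeric((strand_ok & gap_ok) %in% TRUE)
  }
  f
}
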