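#' Convert paired-end input to single-end reads
#'
#' The split-read caller treats every mate as an independent single-end read.
#' For paired input the two streams must be positionally paired; mate
#' suffixes `/1` and `/2` are appended to keep ids unique. Single-end input
#' passes through unchanged.
#'
#' @param fq1 A `read_set` (or FASTQ path) for the first/only stream.
#' @param fq2 Optional second stream.
#' @return A `read_set` with one record per mate, order deterministic
#'   (mate 1 block then mate 2 block).
#' @export
pairs_to_singles <- function(fq1, fq2 = NULL) {
  rs1 <- if (inherits(fq1, "read_set")) fq1 else read_fastq(fq1)
  if (is.null(fq2)) return(rs1)
  rs2 <- if (inherits(fq2, "read_set")) fq2 else read_fastq(fq2)
  if (length(rs1) != length(rs2))
    stop(structure(class = c("pair-mismatch", "error", "condition"),
                   list(message = sprintf("pair-mismatch: %d vs %d records",
                                          length(rs1), length(rs2)),
                        call = NULL)))
  read_set(id = c(paste0(rs1$id, "/1"), paste0(rs2$id, "/2")),
           seq = c(rs1$seq, rs2$seq),
           qual = c(rs1$qual, rs2$qual))
}

#' Select reads near the nominal library length
#'
#' Keeps reads whose length is within `length_tolerance` nt of the
#' configured read length (libraries pooled from runs of different lengths
#' are reduced to the dominant one this way).
#'
#' @param reads A `read_set`.
#' @param cfg A `te_config`.
#' @return Filtered `read_set`.
#' @export
length_filter <- function(reads, cfg) {
  keep <- abs(nchar(reads$seq) - cfg$read_len) <= cfg$length_tolerance
  subset_reads(reads, keep)
}

#' Quality-trim reads
#'
#' Removes leading bases with Phred quality below `qual_leading`, then
#' trailing bases below `qual_trailing`; a read whose remaining mean quality
#' is below `qual_avg_min` (or which trims away entirely) is discarded.
#' Never lengthens a read and is idempotent on its own output.
#'
#' @param reads A `read_set`.
#' @param cfg A `te_config`.
#' @return List with `reads` (trimmed survivors) and `n_discarded`.
#' @export
quality_trim <- function(reads, cfg) {
  tr <- cpp_quality_trim(reads$qual, as.integer(cfg$qual_leading),
                         as.integer(cfg$qual_trailing), cfg$qual_avg_min)
  keep <- tr$to >= tr$from
  out <- read_set(id = reads$id[keep],
                  seq = substr(reads$seq[keep], tr$from[keep], tr$to[keep]),
                  qual = substr(reads$qual[keep], tr$from[keep], tr$to[keep]))
  list(reads = out, n_discarded = sum(!keep))
}

#' Remove reads that map end-to-end to the reference or auxiliary sets
#'
#' Given per-read mappability flags (a hit anywhere removes the read), emits
#' only reads with no accepted end-to-end hit to the reference genome and
#' none to the auxiliary sequence sets (TE consensus, viruses, structural
#' RNAs). The survivors are the "unmappable" input to split-read analysis:
#' junction reads whose two halves come from different places cannot map
#' end-to-end within the mismatch caps.
#'
#' @param reads A `read_set`.
#' @param ref_mapped Logical vector (parallel to reads) or character vector
#'   of read ids with an accepted reference hit.
#' @param aux_mapped Same, for the auxiliary sets.
#' @return `read_set` of split-read input.
#' @export
subtract_full_mappers <- function(reads, ref_mapped, aux_mapped) {
  as_flag <- function(x) {
    if (is.logical(x)) {
      stopifnot(length(x) == length(reads))
      x
    } else reads$id %in% x
  }
  subset_reads(reads, !as_flag(ref_mapped) & !as_flag(aux_mapped))
}

#' Prepare raw reads for split-read analysis
#'
#' Runs the full preparation chain: pair splitting, length selection,
#' quality trimming (reads falling below `2*terminus_len + 1` nt after
#' trimming are routed to the length discard, since terminus extraction
#' would be degenerate), end-to-end mapping to the reference genome (which
#' doubles as the coverage source) and subtraction of reads fully mapping to
#' the reference or to the TE/auxiliary sets. Every input read lands in
#' exactly one class: genome-mapped, aux-mapped, split-input,
#' quality-discarded or length-discarded.
#'
#' @param fq1,fq2 Read input (read_set or FASTQ path; fq2 optional).
#' @param genome_idx `seq_index` of the reference genome (unmasked).
#' @param aux_idx `seq_index` of the TE consensus (plus any virus/structural
#'   RNA records), or a list of such indexes.
#' @param cfg A `te_config`.
#' @return List with `split_reads` (read_set), `coverage`
#'   (a `coverage_source` from the confident reference alignments), and
#'   `log` (data.frame stage/reads_in/reads_out plus a class tally attr).
#' @export
prepare_reads <- function(fq1, fq2 = NULL, genome_idx, aux_idx, cfg) {
  validate_config(cfg)
  rs <- pairs_to_singles(fq1, fq2)
  n_input <- length(rs)

  rs_len <- length_filter(rs, cfg)
  n_len <- length(rs_len)

  qt <- quality_trim(rs_len, cfg)
  rs_trim <- qt$reads
  min_len <- 2L * cfg$terminus_len + 1L
  too_short <- nchar(rs_trim$seq) < min_len
  n_short <- sum(too_short)
  rs_trim <- subset_reads(rs_trim, !too_short)

  gmap <- map_batch(rs_trim$seq, genome_idx, max_mm = cfg$mm_max_depl)
  cov <- coverage_from_map(gmap$summary, nchar(rs_trim$seq), cfg)
  genome_hit <- gmap$summary$n_total >= 1L
  rs_unm <- subset_reads(rs_trim, !genome_hit)

  if (inherits(aux_idx, "seq_index")) aux_idx <- list(aux_idx)
  aux_hit <- rep(FALSE, length(rs_unm))
  for (ai in aux_idx) {
    amap <- map_batch(rs_unm$seq, ai, max_mm = cfg$mm_max_depl)
    aux_hit <- aux_hit | amap$summary$n_total >= 1L
  }
  split_reads <- subset_reads(rs_unm, !aux_hit)

  tally <- c(genome_mapped = sum(genome_hit),
             aux_mapped = sum(aux_hit),
             split_input = length(split_reads),
             quality_discarded = qt$n_discarded,
             length_discarded = (n_input - n_len) + n_short)
  log <- data.frame(
    stage = c("input", "length_filter", "quality_trim", "post_trim_length",
              "genome_subtract", "aux_subtract"),
    reads_in = c(n_input, n_input, n_len, length(qt$reads),
                 length(rs_trim) + 0L, length(rs_unm)),
    reads_out = c(n_input, n_len, length(qt$reads), length(rs_trim),
                  length(rs_unm), length(split_reads)),
    stringsAsFactors = FALSE)
  attr(log, "tally") <- tally
  list(split_reads = split_reads, coverage = cov, log = log)
}
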