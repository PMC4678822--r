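#' Build a sequence index for the internal mapper
#'
#' Validates a FASTA set (non-empty sequences, unique record names) and
#' returns a light index object the batch mapper consumes. Seeding itself is
#' done in compiled code at mapping time; this object fixes the target order
#' (as given) and caches lengths.
#'
#' @param fasta Path, `DNAStringSet` or named character vector.
#' @return An object of class `seq_index`.
#' @export
build_index <- function(fasta) {
  seqs <- load_fasta(fasta)
  if (length(seqs) == 0 || any(nchar(seqs) == 0)) stop("empty FASTA")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) stop("unnamed FASTA record")
  if (anyDuplicated(names(seqs)))
    stop(structure(class = c("duplicate-name", "error", "condition"),
                   list(message = paste0("duplicate-name: ",
                                         names(seqs)[duplicated(names(seqs))][1]),
                        call = NULL)))
  structure(list(names = names(seqs), seqs = unname(seqs),
                 lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  cat(sprintf("seq_index: %d sequence(s), %d nt total\n",
              length(x$names), sum(x$lengths)))
  invisible(x)
}

# Batch mapping summary: one row per query with the total alignment count,
# the count at the best mismatch level, and the best hit (ties broken by
# mismatches, then target order in the index, then position, then + strand).
map_batch <- function(queries, idx, max_mm, max_hits_report = 0L) {
  stopifnot(inherits(idx, "seq_index"))
  res <- cpp_map_batch(idx$seqs, as.character(queries), as.integer(max_mm),
                       as.integer(max_hits_report))
  summary <- data.frame(
    n_total = res$n_total,
    n_best = res$n_best,
    target = ifelse(is.na(res$best_target), NA_character_,
                    idx$names[res$best_target]),
    pos = res$best_pos,
    strand = ifelse(is.na(res$best_strand), NA_character_,
                    c("+", "-")[res$best_strand + 1L]),
    mismatches = res$best_mm,
    stringsAsFactors = FALSE)
  hits <- data.frame(
    query = res$hit_query,
    target = idx$names[res$hit_target],
    pos = res$hit_pos,
    strand = c("+", "-")[res$hit_strand + 1L],
    mismatches = res$hit_mm,
    stringsAsFactors = FALSE)
  list(summary = summary, hits = hits)
}

#' Map queries end-to-end with a mismatch cap
#'
#' Deterministic Hamming (no indels) end-to-end mapping of each query against
#' every position of every indexed target, both strands, with at most
#' `max_mm` mismatches. Reporting follows suppression semantics borrowed from
#' short-read mappers' `-m` option: if a query has more than `max_hits`
#' alignments in total, none are reported, but the true total is still
#' recorded. `N` in a query or target never matches anything.
#'
#' @param queries Character vector of query sequences (each at least
#'   `4*(max_mm+1)` nt so seeding is sound).
#' @param idx A `seq_index` from [build_index()].
#' @param max_mm Maximum mismatches over the full query length.
#' @param max_hits Suppression threshold on the total alignment count.
#' @return data.frame of hits with columns query (1-based query index),
#'   target, pos (0-based), strand, mismatches, n_targets_hit (the query's
#'   total alignment count). Queries whose total exceeds `max_hits`
#'   contribute no rows. The per-query summary (including totals for
#'   suppressed queries) is attached as `attr(, "summary")`.
#' @export
map_end_to_end <- function(queries, idx, max_mm, max_hits) {
  res <- map_batch(queries, idx, max_mm, max_hits_report = max_hits)
  hits <- res$hits
  hits$n_targets_hit <- res$summary$n_total[hits$query]
  hits <- hits[hits$n_targets_hit <= max_hits, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "summary") <- res$summary
  hits
}

#' Hard-mask a genome with a repeat track
#'
#' Replaces every base inside any interval of a RepeatMasker-style BED track
#' with `N`, preserving sequence lengths; overlapping intervals are masked
#' once (union).
#'
#' @param genome Path, `DNAStringSet` or named character vector.
#' @param rm_track BED data.frame (chrom, start, end, ...) or path.
#' @return Named character vector of masked sequences.
#' @export
mask_genome <- function(genome, rm_track) {
  seqs <- load_fasta(genome)
  rm <- load_bed(rm_track)
  if (is.null(rm) || nrow(rm) == 0) return(seqs)
  if (!all(rm$chrom %in% names(seqs)))
    stop("interval-out-of-bounds: unknown chromosome in mask track")
  out <- Biostrings::DNAStringSet(seqs)
  for (ch in unique(rm$chrom)) {
    sub <- rm[rm$chrom == ch, , drop = FALSE]
    len <- nchar(seqs[[ch]])
    if (any(sub$start < 0) || any(sub$end > len) || any(sub$start >= sub$end))
      stop("interval-out-of-bounds")
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    out[[ch]] <- Biostrings::replaceAt(
      out[[ch]], ir,
      Biostrings::DNAStringSet(vapply(IRanges::width(ir),
                                      function(w) strrep("N", w), "")))
  }
  res <- as.character(out)
  names(res) <- names(seqs)
  res
}

#' Coverage sources
#'
#' A coverage source is the set of confidence-filtered reference-genome
#' alignments the coverage-ratio denominators are counted from. Alignments
#' with confidence below `ref_align_min_conf` are dropped at construction.
#'
#' @param alignments data.frame with chrom, start, end (0-based half-open)
#'   and optionally conf (defaults to accepted).
#' @param cfg A `te_config`.
#' @return Object of class `coverage_source`.
#' @export
coverage_source <- function(alignments, cfg = te_config()) {
  df <- as.data.frame(alignments, stringsAsFactors = FALSE)
  if (is.null(df$conf)) df$conf <- rep(cfg$ref_align_min_conf, nrow(df))
  df <- df[df$conf >= cfg$ref_align_min_conf, c("chrom", "start", "end"),
           drop = FALSE]
  by_chrom <- split(df[c("start", "end")], df$chrom)
  ranges <- lapply(by_chrom, function(d) IRanges::IRanges(d$start + 1L, d$end))
  structure(list(ranges = ranges, n = nrow(df)), class = "coverage_source")
}

#' @export
print.coverage_source <- function(x, ...) {
  cat(sprintf("coverage_source: %d accepted alignments on %d chromosome(s)\n",
              x$n, length(x$ranges)))
  invisible(x)
}

# Coverage source from the internal mapper's genome pass: accepted reads are
# those whose best alignment is unique at its mismatch level (the MAPQ >= 10
# contract of the confidence filter).
coverage_from_map <- function(summary, read_len, cfg = te_config()) {
  ok <- summary$n_total >= 1L & summary$n_best == 1L
  df <- data.frame(chrom = summary$target[ok],
                   start = summary$pos[ok],
                   end = summary$pos[ok] + read_len[ok],
                   conf = cfg$ref_align_min_conf,
                   stringsAsFactors = FALSE)
  coverage_source(df, cfg)
}

#' Count accepted alignments over an interval
#'
#' @param src A `coverage_source`.
#' @param iv One interval (list/one-row data.frame with chrom, start, end).
#' @param mode `"any"` counts alignments overlapping the interval by at least
#'   one base (the default, matching `bedtools coverage`); `"within"` counts
#'   only alignments fully contained in it.
#' @return Integer count.
#' @export
coverage_in_interval <- function(src, iv, mode = c("any", "within")) {
  mode <- match.arg(mode)
  stopifnot(inherits(src, "coverage_source"))
  r <- src$ranges[[as.character(iv$chrom)]]
  if (is.null(r)) return(0L)
  q <- IRanges::IRanges(as.integer(iv$start) + 1L, as.integer(iv$end))
  if (mode == "any") {
    IRanges::countOverlaps(q, r, type = "any")
  } else {
    sum(IRanges::countOverlaps(r, q, type = "within") > 0L)
  }
}

#' Local-alignment score ratio against a genome
#'
#' Computes, for each query, the best local-alignment score of the query
#' anywhere in the genome (either strand) divided by the query length, with
#' match +1, mismatch -1, gap open -2, gap extension -1 and a floor of 0.
#' A read lying entirely in the genome scores ~1; a genuine junction read
#' scores roughly the genomic fraction of its length. This is the stand-in
#' for the BLAT score/length ratio used to discard reads from unannotated
#' repeats.
#'
#' By default alignment is seeded on exact 8-mers and completed by full
#' local alignment inside padded, merged candidate windows; alignments whose
#' best-scoring region contains no exact 8-mer (possible only for very weak,
#' sub-threshold similarities) may be underestimated. `exhaustive = TRUE`
#' aligns against every full target instead (quadratic; for small targets
#' and verification).
#'
#' @param queries Character vector of read sequences.
#' @param genome Path, `DNAStringSet`, named character vector or `seq_index`.
#' @param exhaustive Use full quadratic alignment over whole targets.
#' @param seed_len Exact-seed length for the windowed mode.
#' @return Numeric vector of ratios in `[0, 1]` (marginally above 1 is
#'   impossible since match = +1).
#' @export
local_align_ratio <- function(queries, genome, exhaustive = FALSE, seed_len = 8L) {
  seqs <- if (inherits(genome, "seq_index")) genome$seqs else unname(load_fasta(genome))
  cpp_local_ratio(seqs, as.character(queries), as.integer(seed_len),
                  isTRUE(exhaustive), 1L, -1L, 2L, 1L)
}
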