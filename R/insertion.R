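#' Extract the 5' and 3' termini of a read
#'
#' The split-read signal lives in the read ends: the first and last
#' `terminus_len` (default 22) bases are mapped independently. Reads shorter
#' than `2*terminus_len + 1` nt are rejected, since the two termini would
#' cover the whole read.
#'
#' @param reads A `read_set` (or character vector of sequences).
#' @param cfg A `te_config`.
#' @return List with character vectors `t5` and `t3` (orientation preserved).
#' @export
extract_termini <- function(reads, cfg) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  n <- nchar(seqs)
  k <- cfg$terminus_len
  if (any(n < 2L * k + 1L))
    stop(structure(class = c("read-too-short", "error", "condition"),
                   list(message = "read-too-short", call = NULL)))
  list(t5 = substr(seqs, 1L, k), t3 = substr(seqs, n - k + 1L, n))
}

# mapping summaries for both termini against the TE consensus and the
# masked genome, at the insertion branch's caps
map_termini_insertion <- function(termini, te_idx, masked_idx, cfg) {
  list(
    t5_te = map_batch(termini$t5, te_idx, cfg$te_mm_max)$summary,
    t3_te = map_batch(termini$t3, te_idx, cfg$te_mm_max)$summary,
    t5_gen = map_batch(termini$t5, masked_idx, cfg$genome_mm_max_ins)$summary,
    t3_gen = map_batch(termini$t3, masked_idx, cfg$genome_mm_max_ins)$summary)
}

#' Classify reads as insertion candidates
#'
#' A read is an insertion candidate iff exactly one terminus maps uniquely
#' to the (hard-masked) genome and the other terminus has between 1 and
#' `te_hits_max` TE-consensus alignments (more are suppressed, mirroring a
#' mapper's `-m` option). The unique genome hit becomes the anchor; the TE
#' family is taken from the other terminus' best (fewest-mismatch) hit, ties
#' broken by family name order.
#'
#' @param reads A `read_set` of split-read input.
#' @param maps Result of the terminus mapping (see internals), or NULL to
#'   compute from `te_idx`/`masked_idx`.
#' @param te_idx,masked_idx `seq_index` objects (TE consensus; hard-masked
#'   genome). The TE index should list families in lexicographic order so
#'   tie-breaking is by name.
#' @param cfg A `te_config`.
#' @return data.frame of candidates: read_id, chrom, anchor_start, strand,
#'   anchored_end ("5p"/"3p"), te_family, te_mm, blat_ratio (NA until
#'   [validate_blat()]).
#' @export
classify_insertion_reads <- function(reads, te_idx = NULL, masked_idx = NULL,
                                     cfg = te_config(), maps = NULL) {
  if (is.null(maps)) {
    termini <- extract_termini(reads, cfg)
    maps <- map_termini_insertion(termini, te_idx, masked_idx, cfg)
  }
  g5u <- maps$t5_gen$n_total == 1L
  g3u <- maps$t3_gen$n_total == 1L
  te5 <- maps$t5_te$n_total >= 1L & maps$t5_te$n_total <= cfg$te_hits_max
  te3 <- maps$t3_te$n_total >= 1L & maps$t3_te$n_total <= cfg$te_hits_max
  is5 <- g5u & !g3u & te3   # 5' terminus anchors, 3' terminus in TE
  is3 <- g3u & !g5u & te5   # 3' terminus anchors, 5' terminus in TE
  anchored <- ifelse(is5, "5p", ifelse(is3, "3p", NA))
  keep <- !is.na(anchored)
  idx <- which(keep)
  anchor <- data.frame(
    chrom = ifelse(anchored[idx] == "5p", maps$t5_gen$target[idx],
                   maps$t3_gen$target[idx]),
    pos = ifelse(anchored[idx] == "5p", maps$t5_gen$pos[idx],
                 maps$t3_gen$pos[idx]),
    strand = ifelse(anchored[idx] == "5p", maps$t5_gen$strand[idx],
                    maps$t3_gen$strand[idx]),
    stringsAsFactors = FALSE)
  te <- data.frame(
    family = ifelse(anchored[idx] == "5p", maps$t3_te$target[idx],
                    maps$t5_te$target[idx]),
    mm = ifelse(anchored[idx] == "5p", maps$t3_te$mismatches[idx],
                maps$t5_te$mismatches[idx]),
    stringsAsFactors = FALSE)
  ids <- if (inherits(reads, "read_set")) reads$id else as.character(seq_along(g5u))
  data.frame(read_id = ids[idx],
             chrom = anchor$chrom,
             anchor_start = anchor$pos,
             strand = anchor$strand,
             anchored_end = anchored[idx],
             te_family = te$family,
             te_mm = te$mm,
             blat_ratio = rep(NA_real_, length(idx)),
             stringsAsFactors = FALSE)
}

#' Score candidates' full reads against the genome
#'
#' Populates each candidate's `blat_ratio` with the local-alignment
#' score/length ratio of its full read against the (unmasked) reference
#' genome. No candidate is dropped here; the threshold is applied at cluster
#' level as a mean over member reads.
#'
#' @param candidates Candidate data.frame from [classify_insertion_reads()].
#' @param reads The `read_set` the candidates came from.
#' @param genome Reference genome (path, named character vector or
#'   `seq_index`).
#' @return Candidates with `blat_ratio` filled in.
#' @export
validate_blat <- function(candidates, reads, genome) {
  if (nrow(candidates) == 0) return(candidates)
  pos <- match(candidates$read_id, reads$id)
  if (anyNA(pos)) stop("candidate read id missing from read set")
  candidates$blat_ratio <- local_align_ratio(reads$seq[pos], genome)
  candidates
}

# greedy left-to-right window grouping of sorted positions: a position joins
# the open cluster iff it is within W of the cluster's leftmost member
greedy_window_cluster <- function(pos, W) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  id <- integer(n)
  cur <- 1L
  left <- pos[1L]
  id[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    if (pos[i] - left > W) {
      cur <- cur + 1L
      left <- pos[i]
    }
    id[i] <- cur
  }
  id
}

#' Cluster insertion candidates
#'
#' Candidates are partitioned by (chromosome, anchor strand, TE family) and,
#' within each partition, sorted by anchor start and grouped greedily
#' left-to-right: a candidate joins the open cluster iff its anchor start is
#' within `cluster_window` nt of the cluster's leftmost anchor. Every
#' candidate lands in exactly one cluster.
#'
#' @param candidates Candidate data.frame.
#' @param cfg A `te_config`.
#' @return data.frame of raw clusters: chrom, start, end (anchor-start
#'   interval, 0-based half-open), strand, te_family, read_count, span
#'   (max - min anchor start), mean_blat_ratio. The member assignment is
#'   attached as `attr(, "members")` (candidates plus a cluster row index).
#' @export
cluster_insertions <- function(candidates, cfg) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), te_family = character(0),
                      read_count = integer(0), span = integer(0),
                      mean_blat_ratio = numeric(0), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0) {
    attr(empty, "members") <- cbind(candidates,
                                    data.frame(cluster = integer(0)))
    return(empty)
  }
  ord <- order(candidates$chrom, candidates$strand, candidates$te_family,
               candidates$anchor_start, candidates$read_id)
  cand <- candidates[ord, , drop = FALSE]
  key <- paste(cand$chrom, cand$strand, cand$te_family, sep = "\r")
  parts <- split(seq_len(nrow(cand)), factor(key, levels = unique(key)))
  cand$cluster <- NA_integer_
  rows <- list()
  cl_id <- 0L
  for (p in parts) {
    ids <- greedy_window_cluster(cand$anchor_start[p], cfg$cluster_window)
    for (g in seq_len(max(ids))) {
      sel <- p[ids == g]
      cl_id <- cl_id + 1L
      cand$cluster[sel] <- cl_id
      a <- cand$anchor_start[sel]
      rows[[cl_id]] <- data.frame(
        chrom = cand$chrom[sel[1]],
        start = min(a),
        end = max(a) + 1L,
        strand = cand$strand[sel[1]],
        te_family = cand$te_family[sel[1]],
        read_count = length(sel),
        span = max(a) - min(a),
        mean_blat_ratio = mean(cand$blat_ratio[sel]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- cand
  out
}

#' Filter raw insertion clusters
#'
#' Keeps clusters with at least `min_cluster_reads` supporting reads, an
#' anchor span strictly greater than `read_len/2 - terminus_len` (a genuine
#' insertion produces junction reads at diverse offsets, so their anchors
#' tile; a pile-up at one offset is an artifact), a mean local-alignment
#' ratio at most `blat_ratio_max`, and no overlap with the exclusion track.
#'
#' @param clusters Raw clusters from [cluster_insertions()] with
#'   `mean_blat_ratio` populated.
#' @param cfg A `te_config`.
#' @param exclusion Optional BED data.frame (or path) of regions to drop.
#' @return Filtered cluster data.frame (member attribute preserved for
#'   surviving clusters).
#' @export
filter_insertion_clusters <- function(clusters, cfg, exclusion = NULL) {
  if (nrow(clusters) == 0) return(clusters)
  span_min <- cfg$read_len / 2 - cfg$terminus_len
  keep <- clusters$read_count >= cfg$min_cluster_reads &
    clusters$span > span_min &
    !is.na(clusters$mean_blat_ratio) &
    clusters$mean_blat_ratio <= cfg$blat_ratio_max
  excl <- load_bed(exclusion)
  if (!is.null(excl) && nrow(excl)) {
    ov <- overlaps_track(clusters, excl)
    keep <- keep & !ov
  }
  mem <- attr(clusters, "members")
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(mem)) {
    kept_ids <- which(keep)
    mem <- mem[mem$cluster %in% kept_ids, , drop = FALSE]
    mem$cluster <- match(mem$cluster, kept_ids)
    attr(out, "members") <- mem
  }
  out
}

# does each interval row overlap any track interval (>=1 base)?
overlaps_track <- function(ivs, track) {
  out <- logical(nrow(ivs))
  for (ch in unique(ivs$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    sel <- ivs$chrom == ch
    if (!nrow(tr)) next
    q <- IRanges::IRanges(ivs$start[sel] + 1L, pmax(ivs$end[sel], ivs$start[sel] + 1L))
    s <- IRanges::IRanges(tr$start + 1L, tr$end)
    out[sel] <- IRanges::countOverlaps(q, s) > 0L
  }
  out
}

#' Coverage ratio for insertion clusters
#'
#' For each cluster, the window is expanded by `terminus_len` nt at its 5'
#' (lower) coordinate and clamped to the chromosome, and
#' CR = read_count / (reference reads in the window + pseudocount). The
#' reference read count comes from a [coverage_source()]. A high CR means
#' the insertion allele dominates the locus in the library; adding reference
#' coverage strictly decreases it, adding supporting reads increases it.
#'
#' @param clusters Cluster data.frame (insertion form).
#' @param cov A `coverage_source`.
#' @param cfg A `te_config`.
#' @param chrom_lens Named vector of chromosome lengths (for clamping).
#' @param mode Overlap mode passed to [coverage_in_interval()].
#' @return Clusters with columns `cr` and `ref_reads` added.
#' @export
insertion_cr <- function(clusters, cov, cfg, chrom_lens, mode = "any") {
  if (nrow(clusters) == 0) {
    clusters$ref_reads <- integer(0); clusters$cr <- numeric(0)
    return(clusters)
  }
  refn <- integer(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    iv <- clamp_interval(
      list(chrom = clusters$chrom[i],
           start = clusters$start[i] - cfg$terminus_len,
           end = clusters$end[i]),
      chrom_lens[[clusters$chrom[i]]])
    refn[i] <- coverage_in_interval(cov, iv, mode = mode)
  }
  clusters$ref_reads <- refn
  clusters$cr <- clusters$read_count / (refn + cfg$pseudocount)
  clusters
}
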