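#' Classify reads as depletion candidates
#'
#' A read supports a depletion (a reference-annotated TE absent from the
#' sample) when both of its termini map uniquely to the hard-masked genome,
#' on the same chromosome with the same orientation, but further apart than
#' the read length: the read spans the excision junction, so its two ends
#' land on the two flanks of the missing element. The gap is measured from
#' the end of the genomic-left terminus alignment to the start of the
#' genomic-right one (the putatively deleted span).
#'
#' @param reads A `read_set` of split-read input.
#' @param masked_idx `seq_index` of the hard-masked genome.
#' @param cfg A `te_config` (termini mapped with `mm_max_depl` mismatches).
#' @param maps Optional precomputed terminus map summaries (`t5`, `t3`).
#' @return data.frame of candidates: read_id, chrom, strand, left_start,
#'   left_end, right_start, gap.
#' @export
classify_depletion_reads <- function(reads, masked_idx = NULL, cfg = te_config(),
                                     maps = NULL) {
  k <- cfg$terminus_len
  if (is.null(maps)) {
    termini <- extract_termini(reads, cfg)
    maps <- list(t5 = map_batch(termini$t5, masked_idx, cfg$mm_max_depl)$summary,
                 t3 = map_batch(termini$t3, masked_idx, cfg$mm_max_depl)$summary)
  }
  t5 <- maps$t5; t3 <- maps$t3
  ok <- t5$n_total == 1L & t3$n_total == 1L &
    !is.na(t5$target) & !is.na(t3$target) &
    t5$target == t3$target & t5$strand == t3$strand
  ok[is.na(ok)] <- FALSE
  left <- pmin(t5$pos, t3$pos)
  right <- pmax(t5$pos, t3$pos)
  gap <- right - (left + k)
  ok <- ok & gap > cfg$read_len
  idx <- which(ok)
  ids <- if (inherits(reads, "read_set")) reads$id else as.character(seq_along(ok))
  data.frame(read_id = ids[idx],
             chrom = t5$target[idx],
             strand = t5$strand[idx],
             left_start = left[idx],
             left_end = left[idx] + k,
             right_start = right[idx],
             gap = gap[idx],
             stringsAsFactors = FALSE)
}

#' Cluster depletion candidates
#'
#' Greedy grouping as in the insertion branch, but applied jointly to both
#' breakpoint sides: candidates are partitioned by (chromosome, strand),
#' sorted by their genomic-left coordinate, and a candidate joins the open
#' cluster iff both its left and its right coordinates are within
#' `cluster_window` nt of the cluster's leftmost respective sides. Clusters
#' below `min_cluster_reads` are dropped, as are clusters overlapping the
#' exclusion track. The reported 5'-side coordinate is the innermost
#' consensus (`five_end` = max of member left-terminus ends), likewise
#' `three_start` = min of member right-terminus starts.
#'
#' @param candidates data.frame from [classify_depletion_reads()].
#' @param cfg A `te_config`.
#' @param exclusion Optional BED data.frame (or path).
#' @return data.frame of clusters: chrom, five_end, three_start, strand,
#'   read_count; member assignment in `attr(, "members")`.
#' @export
cluster_depletions <- function(candidates, cfg, exclusion = NULL) {
  empty <- data.frame(chrom = character(0), five_end = integer(0),
                      three_start = integer(0), strand = character(0),
                      read_count = integer(0), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0) {
    attr(empty, "members") <- cbind(candidates, data.frame(cluster = integer(0)))
    return(empty)
  }
  W <- cfg$cluster_window
  ord <- order(candidates$chrom, candidates$strand, candidates$left_start,
               candidates$right_start, candidates$read_id)
  cand <- candidates[ord, , drop = FALSE]
  key <- paste(cand$chrom, cand$strand, sep = "\r")
  parts <- split(seq_len(nrow(cand)), factor(key, levels = unique(key)))
  cand$cluster <- NA_integer_
  rows <- list()
  cl_id <- 0L
  for (p in parts) {
    open <- integer(0)          # row indices of open cluster
    min_l <- NA_integer_; min_r <- NA_integer_
    flush <- function(sel) {
      cl_id <<- cl_id + 1L
      cand$cluster[sel] <<- cl_id
      rows[[cl_id]] <<- data.frame(
        chrom = cand$chrom[sel[1]],
        five_end = max(cand$left_end[sel]),
        three_start = min(cand$right_start[sel]),
        strand = cand$strand[sel[1]],
        read_count = length(sel),
        stringsAsFactors = FALSE)
    }
    for (i in p) {
      if (length(open) == 0L) {
        open <- i; min_l <- cand$left_start[i]; min_r <- cand$right_start[i]
      } else if (cand$left_start[i] - min_l <= W &&
                 abs(cand$right_start[i] - min_r) <= W) {
        open <- c(open, i)
        min_r <- min(min_r, cand$right_start[i])
      } else {
        flush(open)
        open <- i; min_l <- cand$left_start[i]; min_r <- cand$right_start[i]
      }
    }
    if (length(open)) flush(open)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  keep <- out$read_count >= cfg$min_cluster_reads &
    out$five_end < out$three_start
  excl <- load_bed(exclusion)
  if (!is.null(excl) && nrow(excl)) {
    iv <- data.frame(chrom = out$chrom, start = out$five_end,
                     end = out$three_start, stringsAsFactors = FALSE)
    keep <- keep & !overlaps_track(iv, excl)
  }
  kept_ids <- which(keep)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  mem <- cand[cand$cluster %in% kept_ids, , drop = FALSE]
  mem$cluster <- match(mem$cluster, kept_ids)
  attr(res, "members") <- mem
  res
}

#' Fixed flank intervals for depletion coverage
#'
#' The reference-allele support for a depletion is counted in two fixed
#' windows bracketing the (imprecise) breakpoints:
#' `iv5 = [five_end - 2L/5, five_end + k + L/5)` and
#' `iv3 = [three_start - L/5, three_start + L/5)`, with L the read length
#' and k the terminus length; fractional bounds are rounded half away from
#' zero and the intervals clamped to the chromosome.
#'
#' @param cluster One cluster row (list/data.frame).
#' @param cfg A `te_config`.
#' @param chrom_len Length of the cluster's chromosome.
#' @return List with `iv5` and `iv3` interval lists.
#' @export
depletion_flank_intervals <- function(cluster, cfg, chrom_len) {
  L <- cfg$read_len; k <- cfg$terminus_len
  iv5 <- clamp_interval(list(chrom = cluster$chrom,
                             start = round_half_up(cluster$five_end - 2 * L / 5),
                             end = round_half_up(cluster$five_end + k + L / 5)),
                        chrom_len)
  iv3 <- clamp_interval(list(chrom = cluster$chrom,
                             start = round_half_up(cluster$three_start - L / 5),
                             end = round_half_up(cluster$three_start + L / 5)),
                        chrom_len)
  list(iv5 = iv5, iv3 = iv3)
}

#' Coverage ratio for depletion clusters
#'
#' CR = depletion reads / (pseudocount + mean(RefGen_5p, RefGen_3p)), where
#' RefGen_5p and RefGen_3p count reference-genome reads in the two flank
#' intervals of [depletion_flank_intervals()].
#'
#' @param clusters Depletion cluster data.frame.
#' @param cov A `coverage_source`.
#' @param cfg A `te_config`.
#' @param chrom_lens Named chromosome lengths.
#' @param mode Overlap mode for [coverage_in_interval()].
#' @return Clusters with `ref_5p`, `ref_3p` and `cr` columns added.
#' @export
depletion_cr <- function(clusters, cov, cfg, chrom_lens, mode = "any") {
  if (nrow(clusters) == 0) {
    clusters$ref_5p <- integer(0); clusters$ref_3p <- integer(0)
    clusters$cr <- numeric(0)
    return(clusters)
  }
  r5 <- integer(nrow(clusters)); r3 <- integer(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    fl <- depletion_flank_intervals(clusters[i, ], cfg,
                                    chrom_lens[[clusters$chrom[i]]])
    r5[i] <- coverage_in_interval(cov, fl$iv5, mode = mode)
    r3[i] <- coverage_in_interval(cov, fl$iv3, mode = mode)
  }
  clusters$ref_5p <- r5
  clusters$ref_3p <- r3
  clusters$cr <- clusters$read_count / (cfg$pseudocount + (r5 + r3) / 2)
  clusters
}

#' Keep depletions that span an annotated TE
#'
#' Raw depletion clusters mostly reflect small genomic deletions; only
#' clusters whose span `[five_end, three_start)` overlaps at least one
#' reference TE interval are reported, annotated with the TE's name. When a
#' span overlaps several TEs, the TE whose midpoint is nearest the span
#' midpoint wins (name order breaks exact ties).
#'
#' @param clusters Depletion cluster data.frame.
#' @param rm_track RepeatMasker-style BED data.frame (or path) with a name
#'   column.
#' @return Clusters overlapping a TE, with a `te_name` column.
#' @export
keep_te_depletions <- function(clusters, rm_track) {
  rm <- load_bed(rm_track)
  if (nrow(clusters) == 0) {
    clusters$te_name <- character(0)
    return(clusters)
  }
  te_name <- rep(NA_character_, nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    tr <- rm[rm$chrom == clusters$chrom[i] &
               rm$start < clusters$three_start[i] &
               rm$end > clusters$five_end[i], , drop = FALSE]
    if (!nrow(tr)) next
    mid <- (clusters$five_end[i] + clusters$three_start[i]) / 2
    d <- abs((tr$start + tr$end) / 2 - mid)
    tr <- tr[order(d, tr$name), , drop = FALSE]
    te_name[i] <- tr$name[1]
  }
  keep <- !is.na(te_name)
  mem <- attr(clusters, "members")
  out <- clusters[keep, , drop = FALSE]
  out$te_name <- te_name[keep]
  rownames(out) <- NULL
  if (!is.null(mem)) {
    kept_ids <- which(keep)
    mem <- mem[mem$cluster %in% kept_ids, , drop = FALSE]
    mem$cluster <- match(mem$cluster, kept_ids)
    attr(out, "members") <- mem
  }
  out
}
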