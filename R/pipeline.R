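#' Call TE insertions end-to-end
#'
#' Runs the full insertion branch: read preparation (pair splitting, length
#' selection, quality trimming), subtraction of reads fully mapping to the
#' reference genome or the TE/auxiliary sets, terminus extraction and
#' mapping, candidate classification, local-alignment validation of the
#' full candidate reads, greedy window clustering, cluster filtering,
#' coverage-ratio computation and gene annotation. Deterministic given
#' inputs and configuration.
#'
#' @param fq1,fq2 Read input: a `read_set` or FASTQ path(s); `fq2` optional.
#' @param genome Reference genome (path / named character / `DNAStringSet`).
#' @param te_fasta TE consensus library (one record per family).
#' @param rm_bed RepeatMasker-style TE annotation BED (data.frame or path).
#' @param genes_bed Gene annotation BED.
#' @param exclude_bed Optional exclusion-region BED.
#' @param aux_fasta Optional extra subtraction sets (virus/structural RNA
#'   FASTA), a path/vector or list of them.
#' @param cfg A [te_config()].
#' @param sam Optional SAM path: use these externally produced reference
#'   alignments (MAPQ-filtered) for coverage instead of the internal mapper.
#' @param out_dir Optional directory; if given, writes `insertions.bed`,
#'   `insertion_manifest.tsv`.
#' @return Object of class `c("te_insertions", "te_calls")`: list with
#'   `calls` (data.frame), `manifest`, `cfg`, `n_candidates`.
#' @export
run_insertions <- function(fq1, fq2 = NULL, genome, te_fasta, rm_bed,
                           genes_bed = NULL, exclude_bed = NULL,
                           aux_fasta = NULL, cfg = te_config(), sam = NULL,
                           out_dir = NULL) {
  validate_config(cfg)
  genome_seqs <- load_fasta(genome)
  genome_idx <- build_index(genome_seqs)
  te_seqs <- load_fasta(te_fasta)
  te_seqs <- te_seqs[order(names(te_seqs))]   # lexicographic tie-breaking
  te_idx <- build_index(te_seqs)
  rm <- load_bed(rm_bed)

  aux_list <- list(te_idx)
  if (!is.null(aux_fasta)) {
    if (!is.list(aux_fasta)) aux_fasta <- list(aux_fasta)
    aux_list <- c(aux_list, lapply(aux_fasta, function(a) build_index(load_fasta(a))))
  }

  prep <- prepare_reads(fq1, fq2, genome_idx, aux_list, cfg)
  cov <- if (is.null(sam)) prep$coverage else coverage_from_sam(sam, cfg)

  masked_idx <- build_index(mask_genome(genome_seqs, rm))
  cands <- classify_insertion_reads(prep$split_reads, te_idx, masked_idx, cfg)
  cands <- validate_blat(cands, prep$split_reads, genome_idx)
  raw <- cluster_insertions(cands, cfg)
  kept <- filter_insertion_clusters(raw, cfg, exclusion = exclude_bed)
  kept <- insertion_cr(kept, cov, cfg, genome_idx$lengths)
  kept$gene_annotation <- if (!is.null(genes_bed))
    nearest_gene(kept, genes_bed) else rep(NA_character_, nrow(kept))

  calls <- data.frame(chrom = kept$chrom, start = kept$start, end = kept$end,
                      name = kept$te_family, score = kept$read_count,
                      strand = kept$strand, cr = kept$cr, span = kept$span,
                      mean_blat_ratio = kept$mean_blat_ratio,
                      ref_reads = kept$ref_reads,
                      gene_annotation = kept$gene_annotation,
                      stringsAsFactors = FALSE)
  calls$te_family <- calls$name
  manifest <- build_manifest(prep$log, cfg,
                             list(candidates = nrow(cands),
                                  raw_clusters = nrow(raw),
                                  reported = nrow(calls)))
  res <- structure(list(calls = calls, manifest = manifest, cfg = cfg,
                        n_candidates = nrow(cands)),
                   class = c("te_insertions", "te_calls"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(calls[setdiff(names(calls), "te_family")],
              file.path(out_dir, "insertions.bed"))
    utils::write.table(manifest, file.path(out_dir, "insertion_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Call TE depletions end-to-end
#'
#' Runs the depletion branch: read preparation and subtraction as in
#' [run_insertions()], then both termini of each surviving read are mapped
#' to the hard-masked genome; reads whose termini land uniquely, concordantly
#' and further apart than the read length become depletion candidates, which
#' are clustered jointly on both breakpoint sides, screened against the
#' exclusion track, scored with the two-flank coverage ratio, filtered to
#' spans overlapping an annotated TE, and annotated.
#'
#' @inheritParams run_insertions
#' @return Object of class `c("te_depletions", "te_calls")`.
#' @export
run_depletions <- function(fq1, fq2 = NULL, genome, te_fasta, rm_bed,
                           genes_bed = NULL, exclude_bed = NULL,
                           aux_fasta = NULL, cfg = te_config(), sam = NULL,
                           out_dir = NULL) {
  validate_config(cfg)
  genome_seqs <- load_fasta(genome)
  genome_idx <- build_index(genome_seqs)
  te_seqs <- load_fasta(te_fasta)
  te_seqs <- te_seqs[order(names(te_seqs))]
  te_idx <- build_index(te_seqs)
  rm <- load_bed(rm_bed)

  aux_list <- list(te_idx)
  if (!is.null(aux_fasta)) {
    if (!is.list(aux_fasta)) aux_fasta <- list(aux_fasta)
    aux_list <- c(aux_list, lapply(aux_fasta, function(a) build_index(load_fasta(a))))
  }

  prep <- prepare_reads(fq1, fq2, genome_idx, aux_list, cfg)
  cov <- if (is.null(sam)) prep$coverage else coverage_from_sam(sam, cfg)

  masked_idx <- build_index(mask_genome(genome_seqs, rm))
  cands <- classify_depletion_reads(prep$split_reads, masked_idx, cfg)
  clusters <- cluster_depletions(cands, cfg, exclusion = exclude_bed)
  if (cfg$depl_blat_filter && nrow(clusters)) {
    mem <- attr(clusters, "members")
    pos <- match(mem$read_id, prep$split_reads$id)
    mem$blat_ratio <- local_align_ratio(prep$split_reads$seq[pos], genome_idx)
    mr <- tapply(mem$blat_ratio, mem$cluster, mean)
    keep <- clusters$read_count > 0
    keep[as.integer(names(mr))] <- mr <= cfg$blat_ratio_max
    clusters <- clusters[keep, , drop = FALSE]
    rownames(clusters) <- NULL
  }
  clusters <- depletion_cr(clusters, cov, cfg, genome_idx$lengths)
  clusters <- keep_te_depletions(clusters, rm)
  clusters$gene_annotation <- if (!is.null(genes_bed))
    nearest_gene(clusters, genes_bed, start_col = "five_end",
                 end_col = "three_start") else rep(NA_character_, nrow(clusters))

  calls <- data.frame(chrom = clusters$chrom, start = clusters$five_end,
                      end = clusters$three_start, name = clusters$te_name,
                      score = clusters$read_count,
                      strand = rep(".", nrow(clusters)),
                      cr = clusters$cr,
                      gene_annotation = clusters$gene_annotation,
                      stringsAsFactors = FALSE)
  calls$five_end <- calls$start
  calls$three_start <- calls$end
  calls$te_name <- calls$name
  manifest <- build_manifest(prep$log, cfg,
                             list(candidates = nrow(cands),
                                  reported = nrow(calls)))
  res <- structure(list(calls = calls, manifest = manifest, cfg = cfg,
                        n_candidates = nrow(cands)),
                   class = c("te_depletions", "te_calls"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(calls[setdiff(names(calls), c("five_end", "three_start", "te_name"))],
              file.path(out_dir, "depletions.bed"))
    utils::write.table(manifest, file.path(out_dir, "depletion_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

build_manifest <- function(log, cfg, extra) {
  tally <- attr(log, "tally")
  man <- rbind(
    log,
    data.frame(stage = names(tally), reads_in = NA_integer_,
               reads_out = as.integer(tally), stringsAsFactors = FALSE),
    data.frame(stage = names(extra), reads_in = NA_integer_,
               reads_out = as.integer(unlist(extra)), stringsAsFactors = FALSE))
  attr(man, "config") <- cfg
  attr(man, "version") <- as.character(utils::packageVersion("teindel"))
  man
}

#' @export
print.te_calls <- function(x, ...) {
  kind <- if (inherits(x, "te_insertions")) "insertion" else "depletion"
  cat(sprintf("TE %s calls: %d cluster(s) from %d candidate read(s)\n",
              kind, nrow(x$calls), x$n_candidates))
  if (nrow(x$calls)) {
    show <- utils::head(x$calls, 10)
    print(show[, intersect(c("chrom", "start", "end", "name", "score",
                             "strand", "cr"), names(show))], row.names = FALSE)
    if (nrow(x$calls) > 10) cat(sprintf("... and %d more\n", nrow(x$calls) - 10))
  }
  invisible(x)
}

#' @export
summary.te_calls <- function(object, ...) {
  x <- object
  cat(sprintf("%d call(s); families: %s\n", nrow(x$calls),
              paste(sort(unique(x$calls$name)), collapse = ", ")))
  if (nrow(x$calls))
    cat(sprintf("CR: median %.3g, range %.3g-%.3g; reads/cluster: median %d\n",
                stats::median(x$calls$cr), min(x$calls$cr), max(x$calls$cr),
                as.integer(stats::median(x$calls$score))))
  tl <- x$manifest
  cat("pipeline stages:\n")
  print(tl, row.names = FALSE)
  invisible(x)
}
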