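#' Pipeline configuration
#'
#' Creates the configuration object holding every numeric threshold used by
#' the caller. Defaults are the published operating point of the split-read
#' pipeline: 22-nt read termini, a 300-nt clustering window, a minimum of 4
#' supporting reads per cluster, a 0.83 cap on the local-alignment
#' score/length ratio, a MAPQ-like confidence floor of 10 for coverage
#' alignments, a pseudocount of 1 in coverage ratios, 5-kb landscape bins and
#' 1-kb coordinate rounding for cross-sample comparison.
#'
#' @param read_len Nominal library read length L in nt.
#' @param terminus_len Length k of the 5' and 3' read termini mapped
#'   independently (nt).
#' @param cluster_window Maximum genomic window W for grouping split-read
#'   anchors into one cluster (nt).
#' @param min_cluster_reads Minimum supporting reads per reported cluster.
#' @param blat_ratio_max Maximum mean local-alignment score/length ratio a
#'   cluster may have; clusters above it are treated as unannotated-repeat
#'   false positives.
#' @param ref_align_min_conf Minimum confidence (MAPQ-like) for a reference
#'   alignment to count toward coverage.
#' @param pseudocount Pseudocount added to the reference read count in
#'   coverage ratios.
#' @param bin_size Landscape bin width (nt).
#' @param overlap_rounding Rounding unit for cross-sample locus comparison (nt).
#' @param length_tolerance Reads within this many nt of `read_len` are kept.
#' @param te_mm_max Mismatch cap when mapping termini to TE consensus.
#' @param te_hits_max Maximum TE-consensus alignments before a terminus is
#'   suppressed (and maximum families an accepted terminus may hit).
#' @param genome_mm_max_ins Mismatch cap for the genome terminus in the
#'   insertion branch.
#' @param mm_max_depl Mismatch cap for termini in the depletion branch and for
#'   full-read subtraction mapping.
#' @param qual_leading,qual_trailing Phred thresholds for trimming low-quality
#'   leading/trailing bases.
#' @param qual_avg_min Minimum mean Phred quality after trimming.
#' @param min_family_count_profile Families with at least this many calls are
#'   listed individually in family profiles; the rest are aggregated.
#' @param depl_blat_filter Apply the score-ratio filter to depletion clusters
#'   as well (off by default; the published pipeline describes the filter only
#'   for the insertion branch).
#' @return A list of class `te_config`.
#' @export
te_config <- function(read_len = 100L,
                      terminus_len = 22L,
                      cluster_window = 300L,
                      min_cluster_reads = 4L,
                      blat_ratio_max = 0.83,
                      ref_align_min_conf = 10,
                      pseudocount = 1,
                      bin_size = 5000L,
                      overlap_rounding = 1000L,
                      length_tolerance = 10L,
                      te_mm_max = 2L,
                      te_hits_max = 5L,
                      genome_mm_max_ins = 1L,
                      mm_max_depl = 3L,
                      qual_leading = 20,
                      qual_trailing = 20,
                      qual_avg_min = 20,
                      min_family_count_profile = 20L,
                      depl_blat_filter = FALSE) {
  cfg <- list(read_len = as.integer(read_len),
              terminus_len = as.integer(terminus_len),
              cluster_window = as.integer(cluster_window),
              min_cluster_reads = as.integer(min_cluster_reads),
              blat_ratio_max = as.numeric(blat_ratio_max),
              ref_align_min_conf = as.numeric(ref_align_min_conf),
              pseudocount = as.numeric(pseudocount),
              bin_size = as.integer(bin_size),
              overlap_rounding = as.integer(overlap_rounding),
              length_tolerance = as.integer(length_tolerance),
              te_mm_max = as.integer(te_mm_max),
              te_hits_max = as.integer(te_hits_max),
              genome_mm_max_ins = as.integer(genome_mm_max_ins),
              mm_max_depl = as.integer(mm_max_depl),
              qual_leading = as.numeric(qual_leading),
              qual_trailing = as.numeric(qual_trailing),
              qual_avg_min = as.numeric(qual_avg_min),
              min_family_count_profile = as.integer(min_family_count_profile),
              depl_blat_filter = isTRUE(depl_blat_filter))
  class(cfg) <- "te_config"
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Checks the structural invariants of a [te_config()] object: the read must
#' be long enough that its two termini do not cover it entirely
#' (`read_len >= 2*terminus_len + 1`), the score-ratio bound must be a
#' fraction in (0, 1], all counts must be non-negative and the clustering
#' window positive. Optionally checks that configured sizes make sense for a
#' given genome.
#'
#' @param cfg A `te_config` object.
#' @param genome_meta Optional named vector of chromosome lengths.
#' @return `cfg`, invisibly unchanged, if valid; otherwise signals an error
#'   of class `invalid-config` naming the violated field.
#' @export
validate_config <- function(cfg, genome_meta = NULL) {
  bad <- function(field) {
    stop(structure(class = c("invalid-config", "error", "condition"),
                   list(message = paste0("invalid-config: ", field),
                        call = sys.call(-1))))
  }
  if (!inherits(cfg, "te_config")) bad("class")
  if (cfg$read_len < 2L * cfg$terminus_len + 1L) bad("read_len")
  if (cfg$terminus_len < 1L) bad("terminus_len")
  if (!(cfg$blat_ratio_max > 0 && cfg$blat_ratio_max <= 1)) bad("blat_ratio_max")
  if (cfg$cluster_window <= 0L) bad("cluster_window")
  counts <- c("min_cluster_reads", "pseudocount", "bin_size", "overlap_rounding",
              "length_tolerance", "te_mm_max", "te_hits_max",
              "genome_mm_max_ins", "mm_max_depl", "min_family_count_profile")
  for (f in counts) if (is.na(cfg[[f]]) || cfg[[f]] < 0) bad(f)
  if (cfg$ref_align_min_conf < 0) bad("ref_align_min_conf")
  if (!is.null(genome_meta)) {
    if (is.null(names(genome_meta)) || any(genome_meta <= 0)) bad("genome_meta")
    if (min(genome_meta) < cfg$read_len)
      warning("some chromosomes are shorter than the read length")
  }
  invisible(cfg)
}

#' Genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)` throughout the package, the
#' BED convention. Strand is one of `"+"`, `"-"` or `"."` (unstranded).
#'
#' @param chrom,start,end,strand Vectors defining the intervals.
#' @return A data.frame with columns chrom, start, end, strand.
#' @export
genome_interval <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   strand = rep(as.character(strand), length.out = length(chrom)),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$strand %in% c("+", "-", ".")))
  df
}

#' Clamp an interval to a chromosome
#'
#' Clips `start` and `end` into `[0, chrom_len]`, preserving order. Used
#' wherever an interval is arithmetically expanded (e.g. the 22-nt expansion
#' of a cluster window before coverage counting) and may run off an end.
#' Idempotent.
#'
#' @param iv A one-row interval (list/data.frame with chrom, start, end).
#' @param chrom_len Chromosome length in nt.
#' @return The clamped interval.
#' @export
clamp_interval <- function(iv, chrom_len) {
  s <- max(0, as.numeric(iv$start))
  e <- min(as.numeric(chrom_len), as.numeric(iv$end))
  if (s >= e)
    stop(structure(class = c("empty-interval", "error", "condition"),
                   list(message = "empty-interval", call = sys.call(-1))))
  iv$start <- as.integer(s)
  iv$end <- as.integer(e)
  iv
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys mirror the
#' arguments of [te_config()]; unknown keys are an error. Values given on the
#' command line (as a named list in `overrides`) take precedence.
#'
#' @param path Path to the file, or `NULL` for pure defaults/overrides.
#' @param overrides Named list of values overriding the file.
#' @return A validated `te_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      vals[[key]] <- val
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(te_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals <- lapply(vals, function(v) {
    if (is.character(v)) {
      if (toupper(v) %in% c("TRUE", "FALSE")) as.logical(v) else as.numeric(v)
    } else v
  })
  do.call(te_config, vals)
}

#' @export
print.te_config <- function(x, ...) {
  cat("Split-read TE caller configuration\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}

# round half away from zero; used for L/5-style interval bounds and for
# kilobase rounding (base round() is banker's)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
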