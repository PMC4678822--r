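#' Read sets
#'
#' A read set is a light container for reads in memory: parallel character
#' vectors of ids, sequences and Phred+33 quality strings.
#'
#' @param id,seq,qual Parallel character vectors.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq, qual = NULL) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  if (is.null(qual)) qual <- vapply(nchar(seq), function(n) strrep("?", n), "")
  qual <- as.character(qual)
  if (length(id) != length(seq) || length(seq) != length(qual))
    stop("id, seq and qual must have equal length")
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality strings differ in length")
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d reads (lengths %s)\n", length(x),
              if (length(x)) paste(range(nchar(x$seq)), collapse = "-") else "-"))
  invisible(x)
}

subset_reads <- function(rs, keep) {
  structure(list(id = rs$id[keep], seq = rs$seq[keep], qual = rs$qual[keep]),
            class = "read_set")
}

#' Read FASTQ into a read set
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A `read_set`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_set(id = sub("\\s.*$", "", names(x)),
           seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read set as FASTQ
#'
#' @param rs A `read_set`.
#' @param path Output path.
#' @export
write_fastq <- function(rs, path) {
  x <- Biostrings::DNAStringSet(rs$seq)
  names(x) <- rs$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(rs$qual))
  invisible(path)
}

#' Load FASTA sequences as a named character vector
#'
#' Accepts a path, a `DNAStringSet` or an already-named character vector.
#'
#' @param x Sequence source.
#' @return Named uppercase character vector.
#' @export
load_fasta <- function(x) {
  if (is.character(x) && length(x) == 0)
    return(stats::setNames(character(0), character(0)))
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(toupper(out))
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x); names(out) <- names(x)
    return(toupper(out))
  }
  if (is.character(x) && !is.null(names(x))) return(toupper(x))
  stop("cannot interpret sequence input")
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write calls (or any interval table) in extended BED format
#'
#' Standard 6 BED columns (chrom, start, end, name, score, strand; 0-based
#' half-open) followed by any extra columns present, preceded by one header
#' line starting with `#` naming all columns. Rows are sorted by
#' (chrom, start, end, name). A write -> [read_bed()] -> write cycle is
#' byte-identical.
#'
#' @param calls data.frame with at least chrom, start, end; name, score and
#'   strand are filled with defaults if absent.
#' @param path Output path.
#' @export
write_bed <- function(calls, path) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (is.null(calls$name)) calls$name <- "."
  if (is.null(calls$score)) calls$score <- 0L
  if (is.null(calls$strand)) calls$strand <- "."
  core <- c("chrom", "start", "end", "name", "score", "strand")
  extra <- setdiff(names(calls), core)
  calls <- calls[, c(core, extra), drop = FALSE]
  if (nrow(calls))
    calls <- calls[order(calls$chrom, calls$start, calls$end, calls$name), ,
                   drop = FALSE]
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) sprintf("%.6g", v) else as.character(v)
  }
  header <- paste0("#", paste(names(calls), collapse = "\t"))
  body <- if (nrow(calls)) {
    do.call(paste, c(lapply(calls, fmt), sep = "\t"))
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an extended BED file written by [write_bed()] (or any plain BED)
#'
#' @param path Path to the file.
#' @return data.frame with typed columns; numeric-looking extra columns are
#'   converted.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    cols <- if (is.null(header)) c("chrom", "start", "end", "name", "score", "strand") else header
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    out$start <- integer(0); out$end <- integer(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(parts[[1]])
  if (is.null(header)) {
    header <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6))]
    if (ncol > 6) header <- c(header, paste0("V", seq(7, ncol)))
  }
  mat <- matrix(unlist(parts), ncol = ncol, byrow = TRUE)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- header
  for (cn in names(out)) {
    if (cn %in% c("chrom", "name", "strand")) next
    v <- out[[cn]]
    suppressWarnings(num <- as.numeric(v))
    if (!anyNA(num)) {
      out[[cn]] <- if (all(num == floor(num)) && cn %in% c("start", "end", "score"))
        as.integer(num) else num
    }
  }
  out
}

load_bed <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.null(x)) return(NULL)
  read_bed(x)
}

#' Build a coverage source from a SAM text file
#'
#' Minimal ingestion of externally produced reference alignments for coverage
#' counting: only RNAME, POS, MAPQ and the reference span implied by the
#' CIGAR (M/D/N/=/X operations) are used. Unmapped records (FLAG 0x4 or
#' RNAME `*`) are skipped; alignments with MAPQ below the configured
#' confidence floor are dropped.
#'
#' @param path Path to a SAM file.
#' @param cfg A `te_config` (for `ref_align_min_conf`).
#' @return A `coverage_source`.
#' @export
coverage_from_sam <- function(path, cfg = te_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(coverage_source(genome_interval(character(0), integer(0), integer(0))))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  f <- function(i) vapply(parts, `[[`, "", i)
  flag <- as.integer(f(2)); rname <- f(3); pos <- as.integer(f(4))
  mapq <- as.numeric(f(5)); cigar <- f(6)
  keep <- rname != "*" & !bitwAnd(flag, 4L)
  span <- vapply(cigar, cigar_ref_span, 0L, USE.NAMES = FALSE)
  df <- data.frame(chrom = rname, start = pos - 1L, end = pos - 1L + span,
                   conf = mapq, stringsAsFactors = FALSE)[keep & span > 0L, ]
  coverage_source(df, cfg)
}

cigar_ref_span <- function(cig) {
  if (cig == "*") return(0L)
  ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
  n <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("\\d+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}
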