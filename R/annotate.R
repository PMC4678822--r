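#' Annotate calls with the nearest gene
#'
#' For each call interval, reports the gene whose interval overlaps it
#' (relation `exonic`/`intronic` if an exon sub-feature track is supplied,
#' otherwise `within gene`); failing that, the nearest gene within
#' `max_dist` nt (relation `upstream` or `downstream`, relative to the gene's
#' strand); failing that, the literal annotation
#' `"intergenic, not near genes"`.
#'
#' @param calls data.frame with chrom, start, end (an `end` of `three_start`
#'   form is accepted via the `end_col` argument).
#' @param genes BED data.frame (chrom, start, end, name, and optionally
#'   strand) or path.
#' @param max_dist Maximum distance (nt) for a gene to count as nearby.
#' @param exons Optional exon BED for exon/intron resolution.
#' @param end_col Name of the column holding interval ends.
#' @param start_col Name of the column holding interval starts.
#' @return Character vector of annotations, `"<gene> (<relation>)"` or the
#'   intergenic default.
#' @export
nearest_gene <- function(calls, genes, max_dist = 1000L, exons = NULL,
                         start_col = "start", end_col = "end") {
  genes <- load_bed(genes)
  exons <- load_bed(exons)
  n <- nrow(calls)
  out <- rep("intergenic, not near genes", n)
  if (n == 0 || is.null(genes) || nrow(genes) == 0) return(out)
  if (is.null(genes$strand)) genes$strand <- "+"
  for (i in seq_len(n)) {
    s <- calls[[start_col]][i]; e <- calls[[end_col]][i]
    g <- genes[genes$chrom == calls$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    ov <- g$start < e & g$end > s
    if (any(ov)) {
      g <- g[ov, , drop = FALSE]
      # widest-overlap gene wins; name breaks ties
      g <- g[order(-(pmin(g$end, e) - pmax(g$start, s)), g$name), , drop = FALSE]
      rel <- "within gene"
      if (!is.null(exons) && nrow(exons)) {
        ex <- exons[exons$chrom == calls$chrom[i] & exons$name == g$name[1] &
                      exons$start < e & exons$end > s, , drop = FALSE]
        rel <- if (nrow(ex)) "exonic" else "intronic"
      }
      out[i] <- paste0(g$name[1], " (", rel, ")")
    } else {
      dist <- ifelse(g$end <= s, s - g$end, g$start - e)
      j <- order(dist, g$name)[1]
      if (dist[j] <= max_dist) {
        before <- g$end[j] <= s   # gene lies left of the call
        rel <- if (g$strand[j] == "+") {
          if (before) "downstream" else "upstream"
        } else {
          if (before) "upstream" else "downstream"
        }
        out[i] <- paste0(g$name[j], " (", rel, ")")
      }
    }
  }
  out
}

#' Tabulate calls into fixed genomic bins
#'
#' Each call is assigned to the `bin_size` (default 5 kb) bin containing its
#' start coordinate; the sparse table covers every bin holding at least one
#' call and preserves totals.
#'
#' @param insertions,depletions Call data.frames (chrom + start coordinate;
#'   depletions use `five_end` if present). Either may be NULL/empty.
#' @param cfg A `te_config`.
#' @return data.frame chrom, bin_start, insertion_count, depletion_count,
#'   sorted by (chrom, bin_start).
#' @export
fixed_bin_counts <- function(insertions = NULL, depletions = NULL,
                             cfg = te_config()) {
  bin_of <- function(df, start_col) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    paste(df$chrom, (df[[start_col]] %/% cfg$bin_size) * cfg$bin_size,
          sep = "\r")
  }
  ins_col <- "start"
  dep_col <- if (!is.null(depletions) && "five_end" %in% names(depletions))
    "five_end" else "start"
  ki <- bin_of(insertions, ins_col)
  kd <- bin_of(depletions, dep_col)
  keys <- sort(unique(c(ki, kd)))
  if (!length(keys)) {
    return(data.frame(chrom = character(0), bin_start = integer(0),
                      insertion_count = integer(0), depletion_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                    bin_start = as.integer(vapply(parts, `[[`, "", 2)),
                    insertion_count = as.integer(table(factor(ki, levels = keys))),
                    depletion_count = as.integer(table(factor(kd, levels = keys))),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$bin_start), , drop = FALSE]
}

#' Per-family call profile
#'
#' Families with at least `min_family_count_profile` (default 20) calls are
#' listed individually, ranked by count (descending; name order breaks
#' ties); the remainder is aggregated under `"other"`. Totals are preserved.
#' If a family-to-class map (e.g. LTR/LINE/DNA/RC) is supplied, a class
#' breakdown is attached as `attr(, "classes")`.
#'
#' @param calls data.frame with a family column (`te_family` or `te_name` or
#'   `name`).
#' @param cfg A `te_config`.
#' @param class_map Optional named character vector family -> class.
#' @return data.frame family, count.
#' @export
family_profile <- function(calls, cfg = te_config(), class_map = NULL) {
  fam_col <- intersect(c("te_family", "te_name", "name"), names(calls))[1]
  if (is.na(fam_col)) stop("calls carry no family column")
  fam <- calls[[fam_col]]
  counts <- table(fam)
  big <- counts[counts >= cfg$min_family_count_profile]
  big <- big[order(-as.integer(big), names(big))]
  other <- sum(counts[counts < cfg$min_family_count_profile])
  out <- data.frame(family = names(big), count = as.integer(big),
                    stringsAsFactors = FALSE)
  if (other > 0)
    out <- rbind(out, data.frame(family = "other", count = as.integer(other),
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  if (!is.null(class_map)) {
    cls <- class_map[fam]
    cls[is.na(cls)] <- "unknown"
    attr(out, "classes") <- as.data.frame(table(class = cls),
                                          stringsAsFactors = FALSE)
  }
  out
}

#' Compare call landscapes across samples
#'
#' Each call is keyed by its chromosome and its start coordinate rounded to
#' the nearest `overlap_rounding` nt (default 1 kb, half away from zero),
#' absorbing the small coordinate jitter between runs or callers; the result
#' is a locus-by-sample presence matrix suitable for overlap (Euler-style)
#' summaries. Symmetric under permutation of the input sets.
#'
#' @param call_sets Named list of call data.frames (chrom + start; depletion
#'   tables use `five_end`).
#' @param cfg A `te_config`.
#' @return data.frame chrom, locus_kb (rounded units) and one logical column
#'   per sample, rows sorted by (chrom, locus_kb).
#' @export
compare_landscapes <- function(call_sets, cfg = te_config()) {
  stopifnot(length(call_sets) >= 2, !is.null(names(call_sets)))
  key_of <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    sc <- if ("five_end" %in% names(df)) "five_end" else "start"
    unique(paste(df$chrom, round_half_up(df[[sc]] / cfg$overlap_rounding),
                 sep = "\r"))
  }
  keys_by_sample <- lapply(call_sets, key_of)
  all_keys <- sort(unique(unlist(keys_by_sample)))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                    locus_kb = as.integer(vapply(parts, `[[`, "", 2)),
                    stringsAsFactors = FALSE)
  for (nm in names(call_sets)) out[[nm]] <- all_keys %in% keys_by_sample[[nm]]
  out <- out[order(out$chrom, out$locus_kb), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a per-bin call landscape
#'
#' Simple per-chromosome chart of insertion and depletion counts per fixed
#' bin.
#'
#' @param bins Output of [fixed_bin_counts()].
#' @param cfg A `te_config`.
#' @export
plot_landscape <- function(bins, cfg = te_config()) {
  chroms <- unique(bins$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    graphics::plot(b$bin_start / 1e3, b$insertion_count, type = "h", col = "firebrick",
                   xlab = "position (kb)", ylab = "calls / bin", main = ch,
                   ylim = c(0, max(b$insertion_count, b$depletion_count, 1)))
    graphics::points(b$bin_start / 1e3, -0 + b$depletion_count, type = "h",
                     col = "steelblue", lty = 2)
  }
  invisible(bins)
}
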