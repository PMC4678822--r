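#' Specification for a synthetic test world
#'
#' Bundles the knobs of the fixture generator: a toy multi-chromosome
#' genome with embedded, annotated TE copies; a small TE consensus library;
#' planted novel insertions and excised reference copies at a chosen allele
#' fraction; and uniform-coverage, substitution-error reads. Defaults are
#' the package's standard validation regime: a 500-kb genome (2 x 250 kb),
#' 4 TE families of 1-3 kb, 10 homozygous insertions, 5 depletions, 100-nt
#' reads at 50-fold coverage with a 0.2% per-base error rate.
#'
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @param n_chroms,chrom_len Number and length (nt) of chromosomes.
#' @param n_te_families Number of TE families.
#' @param te_len_range Min/max consensus length (nt).
#' @param n_reference_te_copies Annotated TE copies embedded in the
#'   reference (cycled over families).
#' @param n_planted_insertions,n_planted_depletions Planted event counts.
#' @param allele_fraction Fraction of sampled genomes carrying each planted
#'   variant (1 = homozygous strain; 0.5 models a balanced pool).
#' @param depth Fold genome coverage of the read library.
#' @param read_len Read length L (nt).
#' @param error_rate Per-base substitution error rate.
#' @param tsd_len Target-site duplication length at insertions (nt).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_chroms = 2L, chrom_len = 250000L,
                         n_te_families = 4L, te_len_range = c(1000L, 3000L),
                         n_reference_te_copies = 8L,
                         n_planted_insertions = 10L, n_planted_depletions = 5L,
                         allele_fraction = 1, depth = 50, read_len = 100L,
                         error_rate = 0.002, tsd_len = 0L) {
  spec <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
               chrom_len = as.integer(chrom_len),
               n_te_families = as.integer(n_te_families),
               te_len_range = as.integer(te_len_range),
               n_reference_te_copies = as.integer(n_reference_te_copies),
               n_planted_insertions = as.integer(n_planted_insertions),
               n_planted_depletions = as.integer(n_planted_depletions),
               allele_fraction = as.numeric(allele_fraction),
               depth = as.numeric(depth), read_len = as.integer(read_len),
               error_rate = as.numeric(error_rate), tsd_len = as.integer(tsd_len))
  stopifnot(spec$allele_fraction >= 0, spec$allele_fraction <= 1,
            spec$depth > 0, spec$error_rate >= 0, spec$error_rate < 1,
            spec$n_chroms >= 1, length(spec$te_len_range) == 2)
  class(spec) <- "fixture_spec"
  spec
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(DNA_BASES[sample.int(4L, n, replace = TRUE)], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sample `n` positions in [lo, hi] pairwise >= gap apart and >= gap away
# from `avoid` positions; error after too many rejections
sample_spaced <- function(n, lo, hi, gap, avoid = integer(0)) {
  out <- integer(0)
  tries <- 0L
  while (length(out) < n) {
    if (tries > 200L * max(n, 1L))
      stop(structure(class = c("spec-infeasible", "error", "condition"),
                     list(message = "spec-infeasible: cannot satisfy spacing",
                          call = NULL)))
    p <- sample(seq.int(lo, hi), 1L)
    if (all(abs(p - c(out, avoid)) >= gap)) out <- c(out, p)
    tries <- tries + 1L
  }
  sort(out)
}

#' Build a synthetic reference world
#'
#' Generates uniform-random chromosomes, a TE consensus library, and embeds
#' `n_reference_te_copies` exact consensus copies at well-separated
#' positions, recorded in a RepeatMasker-style BED. Arbitrary labeled gene
#' intervals are added for annotation; the exclusion track starts empty.
#' Deterministic under the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return List: `genome` (named character), `te` (named character), `rm`,
#'   `genes`, `exclusion` (BED data.frames), `chrom_lens`, `spec`.
#' @export
make_reference <- function(spec) {
  set.seed(spec$seed)
  te_len <- sample(seq.int(spec$te_len_range[1], spec$te_len_range[2]),
                   spec$n_te_families, replace = TRUE)
  te <- stats::setNames(vapply(te_len, random_dna, ""),
                        sprintf("TE%02d", seq_len(spec$n_te_families)))
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  base <- stats::setNames(vapply(rep(spec$chrom_len, spec$n_chroms),
                                 random_dna, ""), chroms)

  n_cp <- spec$n_reference_te_copies
  fam_of_copy <- rep_len(seq_len(spec$n_te_families), n_cp)
  chrom_of_copy <- rep_len(seq_len(spec$n_chroms), n_cp)
  margin <- 4L * spec$read_len
  gap <- 2L * max(te_len) + 4L * spec$read_len
  genome <- base
  rm_rows <- list()
  for (ci in seq_len(spec$n_chroms)) {
    copies <- which(chrom_of_copy == ci)
    if (!length(copies)) next
    pos <- sample_spaced(length(copies), margin, spec$chrom_len - margin, gap)
    fams <- fam_of_copy[copies]
    # splice left-to-right, tracking the growing offset
    off <- 0L
    segs <- character(0)
    prev <- 0L
    for (j in seq_along(pos)) {
      segs <- c(segs, substr(base[ci], prev + 1L, pos[j]), te[[fams[j]]])
      rm_rows[[length(rm_rows) + 1L]] <- data.frame(
        chrom = chroms[ci], start = pos[j] + off,
        end = pos[j] + off + te_len[fams[j]],
        name = names(te)[fams[j]], score = 0L, strand = "+",
        stringsAsFactors = FALSE)
      off <- off + te_len[fams[j]]
      prev <- pos[j]
    }
    segs <- c(segs, substr(base[ci], prev + 1L, spec$chrom_len))
    genome[ci] <- paste(segs, collapse = "")
  }
  rm <- if (length(rm_rows)) do.call(rbind, rm_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  chrom_lens <- stats::setNames(nchar(genome), chroms)

  gene_rows <- list()
  for (ci in seq_len(spec$n_chroms)) {
    n_genes <- 6L
    gs <- sort(sample.int(chrom_lens[ci] - 3000L, n_genes))
    gene_rows[[ci]] <- data.frame(
      chrom = chroms[ci], start = gs,
      end = gs + sample(1000:3000, n_genes, replace = TRUE),
      name = sprintf("gene%s_%02d", ci, seq_len(n_genes)), score = 0L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  exclusion <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  list(genome = genome, te = te, rm = rm, genes = genes,
       exclusion = exclusion, chrom_lens = chrom_lens, spec = spec)
}

# apply insertion/deletion edits (reference coordinates) to one chromosome
apply_edits <- function(seq, edits) {
  if (!nrow(edits)) return(seq)
  edits <- edits[order(-edits$pos), , drop = FALSE]
  n <- nchar(seq)
  for (i in seq_len(nrow(edits))) {
    if (edits$kind[i] == "insertion") {
      seq <- paste0(substr(seq, 1L, edits$pos[i]), edits$ins[i],
                    substr(seq, edits$pos[i] + 1L, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, edits$pos[i]),
                    substr(seq, edits$end[i] + 1L, nchar(seq)))
    }
  }
  seq
}

#' Plant variants into a reference world
#'
#' Chooses insertion loci (away from annotated TE copies, chromosome ends
#' and each other), inserts full TE consensus sequences there (plus an
#' optional target-site duplication), and cleanly excises
#' `n_planted_depletions` annotated reference copies. The variant haplotype
#' carries every event; the second haplotype is the unmodified reference,
#' and reads are later drawn from the two at
#' `allele_fraction / (1 - allele_fraction)`.
#'
#' @param ref A reference world from [make_reference()].
#' @param spec The [fixture_spec()].
#' @return List: `hap_alt`, `hap_ref` (named character genomes), `truth`
#'   (data.frame kind, chrom, start, end, te_family, allele_fraction),
#'   `ref`, `spec`.
#' @export
plant_variants <- function(ref, spec) {
  set.seed(spec$seed + 1L)
  L <- spec$read_len
  chroms <- names(ref$genome)
  fams <- names(ref$te)

  if (spec$n_planted_depletions > nrow(ref$rm))
    stop("spec-infeasible: fewer reference TE copies than requested depletions")
  depl_rows <- if (spec$n_planted_depletions > 0)
    sort(sample.int(nrow(ref$rm), spec$n_planted_depletions)) else integer(0)

  truth <- list()
  edits_by_chrom <- stats::setNames(
    rep(list(data.frame(kind = character(0), pos = integer(0), end = integer(0),
                        ins = character(0), stringsAsFactors = FALSE)), length(chroms)),
    chroms)

  ins_chrom <- if (spec$n_planted_insertions > 0)
    sort(rep_len(seq_along(chroms), spec$n_planted_insertions)) else integer(0)
  for (ci in unique(ins_chrom)) {
    n_here <- sum(ins_chrom == ci)
    ch <- chroms[ci]
    rm_here <- ref$rm[ref$rm$chrom == ch, , drop = FALSE]
    avoid <- as.integer(c(rbind(rm_here$start, rm_here$end)))
    # keep clear of annotated copies and ends; spacing comfortably over 2L
    pos <- sample_spaced(n_here, 2L * L, ref$chrom_lens[[ch]] - 2L * L,
                         gap = max(2L * L + 1L, 1500L),
                         avoid = avoid)
    # reject positions falling inside an annotated copy (avoid covers edges)
    inside <- vapply(pos, function(p)
      any(p > rm_here$start - L & p < rm_here$end + L), TRUE)
    if (any(inside))
      pos[inside] <- vapply(pos[inside], function(p) {
        repeat {
          p2 <- sample_spaced(1L, 2L * L, ref$chrom_lens[[ch]] - 2L * L,
                              gap = max(2L * L + 1L, 1500L),
                              avoid = c(avoid, pos))
          if (!any(p2 > rm_here$start - L & p2 < rm_here$end + L)) return(p2)
        }
      }, 0L)
    fam_pick <- rep_len(fams, n_here)
    for (j in seq_len(n_here)) {
      tsd <- if (spec$tsd_len > 0)
        substr(ref$genome[[ch]], pos[j] + 1L, pos[j] + spec$tsd_len) else ""
      edits_by_chrom[[ch]] <- rbind(edits_by_chrom[[ch]], data.frame(
        kind = "insertion", pos = pos[j], end = pos[j],
        ins = paste0(ref$te[[fam_pick[j]]], tsd), stringsAsFactors = FALSE))
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "insertion", chrom = ch, start = pos[j], end = pos[j],
        te_family = fam_pick[j], allele_fraction = spec$allele_fraction,
        stringsAsFactors = FALSE)
    }
  }
  for (ri in depl_rows) {
    ch <- ref$rm$chrom[ri]
    edits_by_chrom[[ch]] <- rbind(edits_by_chrom[[ch]], data.frame(
      kind = "depletion", pos = ref$rm$start[ri], end = ref$rm$end[ri],
      ins = "", stringsAsFactors = FALSE))
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "depletion", chrom = ch, start = ref$rm$start[ri],
      end = ref$rm$end[ri], te_family = ref$rm$name[ri],
      allele_fraction = spec$allele_fraction, stringsAsFactors = FALSE)
  }
  hap_alt <- ref$genome
  for (ch in chroms) hap_alt[ch] <- apply_edits(ref$genome[[ch]], edits_by_chrom[[ch]])
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(0), chrom = character(0), start = integer(0),
               end = integer(0), te_family = character(0),
               allele_fraction = numeric(0), stringsAsFactors = FALSE)
  list(hap_alt = hap_alt, hap_ref = ref$genome, truth = truth,
       ref = ref, spec = spec)
}

#' Simulate an error-bearing read library from a donor world
#'
#' Uniform random start positions over both haplotypes (chosen per read with
#' probability `allele_fraction` for the variant haplotype), random strand,
#' per-base substitution errors at `error_rate`, constant Q30 qualities.
#' Read count = `depth * reference genome size / read_len`. Deterministic
#' under the spec seed.
#'
#' @param donor Output of [plant_variants()].
#' @param spec The [fixture_spec()].
#' @return List: `reads` (a `read_set`), `truth` (passed through).
#' @export
simulate_reads <- function(donor, spec) {
  set.seed(spec$seed + 2L)
  L <- spec$read_len
  chroms <- names(donor$hap_ref)
  ref_lens <- nchar(donor$hap_ref)
  n <- as.integer(round(spec$depth * sum(ref_lens) / L))
  use_alt <- stats::runif(n) < spec$allele_fraction
  chrom_i <- sample.int(length(chroms), n, replace = TRUE, prob = ref_lens)
  rev <- stats::runif(n) < 0.5
  seqs <- character(n)
  for (alt in c(TRUE, FALSE)) {
    for (ci in seq_along(chroms)) {
      sel <- which(use_alt == alt & chrom_i == ci)
      if (!length(sel)) next
      src <- if (alt) donor$hap_alt[[ci]] else donor$hap_ref[[ci]]
      starts <- sample.int(nchar(src) - L + 1L, length(sel), replace = TRUE)
      seqs[sel] <- substring(src, starts, starts + L - 1L)
    }
  }
  if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
  if (spec$error_rate > 0) {
    n_err <- stats::rbinom(n, L, spec$error_rate)
    for (i in which(n_err > 0L)) {
      p <- sample.int(L, n_err[i])
      s <- seqs[i]
      for (pp in p) {
        cur <- substr(s, pp, pp)
        substr(s, pp, pp) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
      seqs[i] <- s
    }
  }
  reads <- read_set(id = sprintf("r%07d", seq_len(n)), seq = seqs,
                    qual = rep(strrep("?", L), n))
  list(reads = reads, truth = donor$truth)
}

#' Build a complete synthetic world in one call
#'
#' [make_reference()] + [plant_variants()] + [simulate_reads()].
#'
#' @param spec A [fixture_spec()].
#' @return List: `ref`, `donor`, `reads`, `truth`, `spec`.
#' @export
simulate_world <- function(spec = fixture_spec()) {
  ref <- make_reference(spec)
  donor <- plant_variants(ref, spec)
  sim <- simulate_reads(donor, spec)
  list(ref = ref, donor = donor, reads = sim$reads, truth = sim$truth,
       spec = spec)
}

#' Engineer an unannotated degenerate-repeat locus
#'
#' Models the false-positive mechanism the score-ratio filter exists for: a
#' degenerate repeat copy missed by the annotation track. A diverged copy of
#' one TE family is present in the *reference* at a clean locus (not
#' recorded in the RepeatMasker track, so it is never masked), and the
#' sample carries its own variant of the copy, diverged at the same
#' positions but to different bases. Sample reads over the copy then fail
#' end-to-end mapping to both the reference and the consensus, their
#' termini look like genome + TE junctions (a terminus with few diverged
#' sites anchors uniquely at the unmasked locus while the other still hits
#' the consensus within its mismatch cap), yet the full reads align locally
#' to the reference at a high score ratio - exactly the degenerate-repeat
#' reads the ratio filter must remove. The truth table is empty: any
#' resulting cluster is spurious.
#'
#' @param spec A [fixture_spec()] (its planted-event counts are ignored).
#' @param divergence Per-base divergence of both copies from consensus
#'   (at shared positions).
#' @return A world bundle as from [simulate_world()], with empty truth and
#'   the engineered locus recorded in `fp_locus`.
#' @export
make_fp_world <- function(spec = fixture_spec(), divergence = 0.06) {
  spec$n_planted_insertions <- 0L
  spec$n_planted_depletions <- 0L
  ref <- make_reference(spec)
  set.seed(spec$seed + 3L)
  fam <- names(ref$te)[1]
  te_seq <- ref$te[[fam]]
  ch <- names(ref$genome)[1]
  rm_here <- ref$rm[ref$rm$chrom == ch, , drop = FALSE]
  avoid <- as.integer(c(rbind(rm_here$start, rm_here$end)))
  pos <- sample_spaced(1L, 4L * spec$read_len,
                       ref$chrom_lens[[ch]] - 4L * spec$read_len,
                       gap = 2L * nchar(te_seq), avoid = avoid)
  idx <- which(stats::runif(nchar(te_seq)) < divergence)
  ref_copy <- te_seq      # diverged copy sitting unmasked in the reference
  donor_copy <- te_seq    # the sample's variant of the same copy
  for (p in idx) {
    cur <- substr(te_seq, p, p)
    alt <- sample(setdiff(DNA_BASES, cur), 2L)
    substr(ref_copy, p, p) <- alt[1]
    substr(donor_copy, p, p) <- alt[2]
  }
  splice <- function(s, at, ins)
    paste0(substr(s, 1L, at), ins, substr(s, at + 1L, nchar(s)))
  ref$genome[ch] <- splice(ref$genome[[ch]], pos, ref_copy)
  ref$chrom_lens <- stats::setNames(nchar(ref$genome), names(ref$genome))
  # the annotated-copy track keeps reference coordinates valid downstream
  shift <- nchar(te_seq)
  sel <- ref$rm$chrom == ch & ref$rm$start >= pos
  ref$rm$start[sel] <- ref$rm$start[sel] + shift
  ref$rm$end[sel] <- ref$rm$end[sel] + shift
  sel <- ref$genes$chrom == ch & ref$genes$start >= pos
  ref$genes$start[sel] <- ref$genes$start[sel] + shift
  ref$genes$end[sel] <- ref$genes$end[sel] + shift
  donor_genome <- ref$genome
  donor_genome[ch] <- paste0(substr(ref$genome[[ch]], 1L, pos), donor_copy,
                             substr(ref$genome[[ch]], pos + shift + 1L,
                                    nchar(ref$genome[[ch]])))
  donor <- list(hap_alt = donor_genome, hap_ref = donor_genome,
                truth = data.frame(kind = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   te_family = character(0),
                                   allele_fraction = numeric(0),
                                   stringsAsFactors = FALSE),
                ref = ref, spec = spec)
  sim <- simulate_reads(donor, spec)
  list(ref = ref, donor = donor, reads = sim$reads, truth = donor$truth,
       spec = spec, fp_locus = list(chrom = ch, start = pos,
                                    end = pos + shift, family = fam))
}

#' Compare insertion calls with a planted truth table
#'
#' A planted insertion is recovered when at least one call on its chromosome
#' lies within `tol` nt of the breakpoint with the correct family. Also
#' reports, per call, the distance to the nearest planted breakpoint
#' (family-agnostic), for specificity checks.
#'
#' @param calls Insertion call data.frame (chrom, start, end, te_family).
#' @param truth Truth table from the fixture generator.
#' @param tol Matching tolerance in nt (typically the read length).
#' @return List: `recall`, `recovered` (logical per planted insertion),
#'   `call_dist` (per call, nt to nearest planted breakpoint).
#' @export
evaluate_insertion_calls <- function(calls, truth, tol) {
  tr <- truth[truth$kind == "insertion", , drop = FALSE]
  dist_to <- function(chrom, s, e, bp_chrom, bp) {
    ifelse(chrom != bp_chrom, Inf,
           ifelse(bp < s, s - bp, ifelse(bp > e, bp - e, 0)))
  }
  recovered <- logical(nrow(tr))
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      if (!nrow(calls)) next
      d <- dist_to(calls$chrom, calls$start, calls$end, tr$chrom[i], tr$start[i])
      recovered[i] <- any(d <= tol & calls$te_family == tr$te_family[i])
    }
  }
  call_dist <- if (nrow(calls)) {
    vapply(seq_len(nrow(calls)), function(j) {
      if (!nrow(tr)) return(Inf)
      min(dist_to(calls$chrom[j], calls$start[j], calls$end[j],
                  tr$chrom, tr$start))
    }, 0)
  } else numeric(0)
  list(recall = if (nrow(tr)) mean(recovered) else NA_real_,
       recovered = recovered, call_dist = call_dist)
}

#' Compare depletion calls with a planted truth table
#'
#' A planted depletion is recovered when some call on its chromosome has
#' both cluster-side coordinates within `tol` nt of the excised copy's
#' breakpoints and carries its TE name.
#'
#' @param calls Depletion call data.frame (chrom, five_end, three_start,
#'   te_name).
#' @param truth Truth table.
#' @param tol Matching tolerance in nt.
#' @return List: `recall`, `recovered`, and per-call `spurious` flags.
#' @export
evaluate_depletion_calls <- function(calls, truth, tol) {
  tr <- truth[truth$kind == "depletion", , drop = FALSE]
  recovered <- logical(nrow(tr))
  matched_call <- rep(FALSE, nrow(calls))
  if (nrow(tr) && nrow(calls)) {
    for (i in seq_len(nrow(tr))) {
      hit <- calls$chrom == tr$chrom[i] &
        abs(calls$five_end - tr$start[i]) <= tol &
        abs(calls$three_start - tr$end[i]) <= tol &
        calls$te_name == tr$te_family[i]
      recovered[i] <- any(hit)
      matched_call <- matched_call | hit
    }
  }
  list(recall = if (nrow(tr)) mean(recovered) else NA_real_,
       recovered = recovered, spurious = !matched_call)
}
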