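# Independent reference implementations used as oracles, plus cached
# small synthetic worlds shared across test files.

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Brute-force Hamming scan of one query over every offset of every target,
# both strands. Returns data.frame(target, pos, strand, mismatches).
oracle_hamming <- function(query, targets, max_mm) {
  hits <- list()
  qs <- c(`+` = query, `-` = rc(query))
  ql <- nchar(query)
  for (tn in names(targets)) {
    tseq <- targets[[tn]]
    tl <- nchar(tseq)
    if (tl < ql) next
    for (strand in c("+", "-")) {
      q <- strsplit(qs[[strand]], "")[[1]]
      for (p in 0:(tl - ql)) {
        t <- strsplit(substr(tseq, p + 1, p + ql), "")[[1]]
        mm <- sum(q != t | q == "N" | t == "N")
        if (mm <= max_mm)
          hits[[length(hits) + 1]] <- data.frame(
            target = tn, pos = p, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(data.frame(target = character(0), pos = integer(0),
                                       strand = character(0),
                                       mismatches = integer(0)))
  do.call(rbind, hits)
}

# Set-peeling formulation of greedy window clustering: repeatedly take the
# leftmost remaining position and peel off everything within W of it.
oracle_window_cluster <- function(pos, W) {
  ord <- order(pos)
  pos_s <- pos[ord]
  id <- integer(length(pos_s))
  cl <- 0L
  remaining <- seq_along(pos_s)
  while (length(remaining)) {
    cl <- cl + 1L
    left <- pos_s[remaining[1]]
    take <- remaining[pos_s[remaining] - left <= W]
    id[take] <- cl
    remaining <- setdiff(remaining, take)
  }
  id[order(ord)]   # back to input order
}

# Transparent re-statement of the two-sided depletion grouping rule.
oracle_depletion_cluster <- function(left, right, W) {
  ord <- order(left, right)
  id <- integer(length(left))
  cl <- 0L
  min_l <- min_r <- NA
  for (i in ord) {
    if (cl == 0L || left[i] - min_l > W || abs(right[i] - min_r) > W) {
      cl <- cl + 1L
      min_l <- left[i]; min_r <- right[i]
    } else {
      min_r <- min(min_r, right[i])
    }
    id[i] <- cl
  }
  id
}

# Local-alignment score oracle via Biostrings (match +1 / mismatch -1,
# gap of length g costs 2 + g).
oracle_local_score <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  best <- 0
  for (q in c(query, rc(query))) {
    s <- Biostrings::pairwiseAlignment(q, subject, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1,
                                       scoreOnly = TRUE)
    best <- max(best, s)
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# cached worlds (built once per test run)
.world_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- builder()
  .world_cache[[key]]
}

small_world <- function() cached("small", function() {
  spec <- fixture_spec(seed = 7, n_chroms = 1, chrom_len = 60000,
                       n_te_families = 2, te_len_range = c(800L, 1200L),
                       n_reference_te_copies = 3, n_planted_insertions = 3,
                       n_planted_depletions = 2, depth = 40, read_len = 100,
                       error_rate = 0.002)
  simulate_world(spec)
})

small_clean_world <- function() cached("clean", function() {
  spec <- fixture_spec(seed = 12, n_chroms = 1, chrom_len = 60000,
                       n_te_families = 2, te_len_range = c(800L, 1200L),
                       n_reference_te_copies = 3, n_planted_insertions = 0,
                       n_planted_depletions = 0, depth = 40, read_len = 100,
                       error_rate = 0.002)
  simulate_world(spec)
})

run_ins_world <- function(w, cfg = te_config(), ...)
  run_insertions(w$reads, genome = w$ref$genome, te_fasta = w$ref$te,
                 rm_bed = w$ref$rm, genes_bed = w$ref$genes, cfg = cfg, ...)

run_dep_world <- function(w, cfg = te_config(), ...)
  run_depletions(w$reads, genome = w$ref$genome, te_fasta = w$ref$te,
                 rm_bed = w$ref$rm, genes_bed = w$ref$genes, cfg = cfg, ...)
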