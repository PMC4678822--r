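tiny_spec <- function(...) {
  args <- list(seed = 3, n_chroms = 2, chrom_len = 20000, n_te_families = 2,
               te_len_range = c(500L, 800L), n_reference_te_copies = 4,
               n_planted_insertions = 2, n_planted_depletions = 1,
               depth = 8, read_len = 100, error_rate = 0.001)
  do.call(fixture_spec, utils::modifyList(args, list(...)))
}

test_that("fixture generation is fully deterministic under its seed", {
  s <- tiny_spec()
  w1 <- simulate_world(s)
  w2 <- simulate_world(s)
  expect_identical(w1$ref$genome, w2$ref$genome)
  expect_identical(w1$ref$rm, w2$ref$rm)
  expect_identical(w1$donor$hap_alt, w2$donor$hap_alt)
  expect_identical(w1$reads$seq, w2$reads$seq)
  expect_identical(w1$truth, w2$truth)
  w3 <- simulate_world(tiny_spec(seed = 4))
  expect_false(identical(w1$reads$seq, w3$reads$seq))
})

test_that("the reference embeds exactly the annotated TE copies and nothing else", {
  ref <- make_reference(tiny_spec())
  expect_equal(nrow(ref$rm), 4)
  # every annotated interval contains its family's consensus verbatim
  for (i in seq_len(nrow(ref$rm))) {
    got <- substr(ref$genome[[ref$rm$chrom[i]]], ref$rm$start[i] + 1, ref$rm$end[i])
    expect_identical(got, unname(ref$te[[ref$rm$name[i]]]))
  }
  # TE 22-mers occur nowhere outside the annotated intervals: masking the
  # track and searching the consensus termini finds nothing
  masked <- mask_genome(ref$genome, ref$rm)
  for (fam in names(ref$te)) {
    for (kmer in c(substr(ref$te[[fam]], 1, 22),
                   substr(ref$te[[fam]], nchar(ref$te[[fam]]) - 21,
                          nchar(ref$te[[fam]])))) {
      hits <- Biostrings::vcountPattern(kmer, Biostrings::DNAStringSet(masked)) +
        Biostrings::vcountPattern(rc(kmer), Biostrings::DNAStringSet(masked))
      expect_equal(sum(hits), 0)
    }
  }
})

test_that("planted variants edit the donor by exactly the expected lengths", {
  s <- tiny_spec()
  ref <- make_reference(s)
  donor <- plant_variants(ref, s)
  tr <- donor$truth
  expect_equal(nrow(tr), 3)
  expect_equal(sum(tr$kind == "insertion"), 2)
  ins_len <- sum(nchar(ref$te[tr$te_family[tr$kind == "insertion"]]))
  dep_len <- sum(tr$end[tr$kind == "depletion"] - tr$start[tr$kind == "depletion"])
  expect_equal(sum(nchar(donor$hap_alt)) - sum(nchar(donor$hap_ref)),
               ins_len - dep_len)
  # planted loci respect the stated spacing invariants
  for (ch in unique(tr$chrom)) {
    pos <- sort(tr$start[tr$chrom == ch])
    if (length(pos) > 1) expect_true(all(diff(pos) > 2 * s$read_len))
  }
})

test_that("read simulation hits the depth arithmetic and error model", {
  s <- tiny_spec()
  w <- simulate_world(s)
  expect_length(w$reads, round(s$depth * sum(nchar(w$ref$genome)) / s$read_len))
  expect_true(all(nchar(w$reads$seq) == s$read_len))
  # with error_rate 0 every read is an exact substring of one haplotype
  s0 <- tiny_spec(error_rate = 0)
  w0 <- simulate_world(s0)
  pick <- w0$reads$seq[seq(1, length(w0$reads), by = 97)]
  hay <- Biostrings::DNAStringSet(c(w0$donor$hap_alt, w0$donor$hap_ref))
  for (rd in pick) {
    n <- sum(Biostrings::vcountPattern(rd, hay)) +
      sum(Biostrings::vcountPattern(rc(rd), hay))
    expect_gte(n, 1)
  }
})

test_that("allele fraction halves the variant-junction read yield", {
  # a read spanning the excision junction can only come from the variant
  # haplotype; its 44-mer signature is countable directly in the read pool
  junction_reads <- function(seed, f) {
    s <- tiny_spec(seed = seed, allele_fraction = f, error_rate = 0,
                   n_planted_insertions = 0, n_planted_depletions = 1)
    w <- simulate_world(s)
    bp <- w$truth$start[w$truth$kind == "depletion"]
    ch <- w$truth$chrom[w$truth$kind == "depletion"]
    sig <- substr(w$donor$hap_alt[[ch]], bp - 21, bp + 22)
    pool <- Biostrings::DNAStringSet(w$reads$seq)
    sum(Biostrings::vcountPattern(sig, pool)) +
      sum(Biostrings::vcountPattern(rc(sig), pool))
  }
  n_full <- vapply(1:10, junction_reads, 0, f = 1)
  n_half <- vapply(1:10, junction_reads, 0, f = 0.5)
  expect_gt(mean(n_full), 0)
  ratio <- mean(n_half) / mean(n_full)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("junction coverage matches the depth x (L-2k)/L expectation", {
  # for a homozygous insertion, reads usable as split candidates must cover
  # the breakpoint with >= 22 nt on both sides: about depth * (L - 2k) / L
  s <- tiny_spec(n_planted_insertions = 2, n_planted_depletions = 0,
                 depth = 30, error_rate = 0)
  per_event <- c()
  for (seed in 1:20) {
    s$seed <- seed
    w <- simulate_world(s)
    ins <- w$truth[w$truth$kind == "insertion", ]
    prep <- prepare_reads(w$reads, NULL, build_index(w$ref$genome),
                          build_index(w$ref$te), te_config())
    cand <- classify_insertion_reads(prep$split_reads,
                                     build_index(w$ref$te),
                                     build_index(mask_genome(w$ref$genome, w$ref$rm)),
                                     te_config())
    for (i in seq_len(nrow(ins))) {
      n <- sum(cand$chrom == ins$chrom[i] &
                 abs(cand$anchor_start - ins$start[i]) <= s$read_len)
      per_event <- c(per_event, n)
    }
  }
  # two junctions per insertion, each sampled at ~depth*(L-2k)/L; allow a
  # generous band around the 2 * 30 * 56/100 = 33.6 expectation
  expect_gt(mean(per_event), 0.6 * 2 * 30 * 56 / 100)
  expect_lt(mean(per_event), 1.4 * 2 * 30 * 56 / 100)
})
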