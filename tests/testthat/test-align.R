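test_that("index construction validates its input", {
  expect_s3_class(build_index(c(chr1 = random_seq(1000))), "seq_index")
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(c(a = "ACGT", a = "ACGT")), class = "duplicate-name")
})

test_that("end-to-end mapping agrees with a brute-force Hamming scan", {
  set.seed(101)
  targets <- c(chr1 = random_seq(3000), chr2 = random_seq(2000))
  idx <- build_index(targets)
  for (rep_i in 1:30) {
    mm_cap <- sample(0:3, 1)
    if (runif(1) < 0.7) {
      # genomic 22-mer, possibly mutated and/or reverse-complemented
      ch <- sample(names(targets), 1)
      p <- sample(nchar(targets[[ch]]) - 22, 1)
      q <- substr(targets[[ch]], p, p + 21)
      nmut <- sample(0:mm_cap, 1)
      if (nmut > 0) {
        qq <- strsplit(q, "")[[1]]
        at <- sample(22, nmut)
        qq[at] <- vapply(qq[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
        q <- paste(qq, collapse = "")
      }
      if (runif(1) < 0.5) q <- rc(q)
    } else {
      q <- random_seq(22)
    }
    got <- map_end_to_end(q, idx, mm_cap, max_hits = 1000)
    want <- oracle_hamming(q, targets, mm_cap)
    expect_equal(attr(got, "summary")$n_total, nrow(want))
    if (nrow(want)) {
      got_k <- with(got, sort(paste(target, pos, strand, mismatches)))
      want_k <- with(want, sort(paste(target, pos, strand, mismatches)))
      expect_equal(got_k, want_k)
    }
  }
})

test_that("multiplicity suppression hides repetitive queries but records the count", {
  set.seed(5)
  q <- random_seq(22)
  genome <- paste0(random_seq(500),
                   paste(rep(paste0(q, random_seq(50)), 6), collapse = ""),
                   random_seq(500))
  idx <- build_index(c(chr1 = genome))
  got <- map_end_to_end(q, idx, 0, max_hits = 5)
  expect_equal(nrow(got), 0)
  expect_equal(attr(got, "summary")$n_total, 6)
  # raising the cap reveals all six
  got6 <- map_end_to_end(q, idx, 0, max_hits = 6)
  expect_equal(nrow(got6), 6)
})

test_that("a unique 22-mer maps once; its reverse complement maps on the minus strand", {
  set.seed(6)
  genome <- c(chr1 = random_seq(5000))
  q <- substr(genome[[1]], 1201, 1222)
  idx <- build_index(genome)
  fwd <- map_end_to_end(q, idx, 0, 5)
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$pos, 1200)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$mismatches, 0)
  rev <- map_end_to_end(rc(q), idx, 0, 5)
  expect_equal(rev$pos, 1200)
  expect_equal(rev$strand, "-")
})

test_that("hard masking replaces interval unions with N and kills mapping there", {
  genome <- c(chr1 = random_seq(400))
  expect_equal(mask_genome(genome, NULL), genome)
  m <- mask_genome(genome, data.frame(chrom = "chr1", start = 10, end = 20))
  expect_equal(nchar(m), nchar(genome))
  expect_equal(substr(m[[1]], 11, 20), strrep("N", 10))
  expect_equal(substr(m[[1]], 1, 10), substr(genome[[1]], 1, 10))
  # overlapping intervals mask their per-base union exactly once
  ov <- mask_genome(genome, data.frame(chrom = "chr1",
                                       start = c(50, 60), end = c(70, 90)))
  masked_pos <- which(strsplit(ov[[1]], "")[[1]] == "N")
  expect_equal(masked_pos, 51:90)
  expect_error(mask_genome(genome, data.frame(chrom = "chr1", start = 390, end = 410)),
               "interval-out-of-bounds")
  # a query overlapping masked bases can no longer align there
  q <- substr(genome[[1]], 6, 27)   # overlaps the [10,20) mask by 15 bases
  idx_m <- build_index(m)
  expect_equal(attr(map_end_to_end(q, idx_m, 3, 5), "summary")$n_total, 0)
})

test_that("interval coverage counts overlapping accepted alignments", {
  aln <- data.frame(chrom = "chr1",
                    start = c(100, 150, 180, 400, 90),
                    end = c(200, 250, 280, 500, 205),
                    conf = c(30, 30, 30, 30, 5))
  src <- coverage_source(aln, te_config())
  iv <- list(chrom = "chr1", start = 120, end = 260)
  expect_equal(coverage_in_interval(src, iv), 3L)   # low-conf row dropped
  # alignment straddling the boundary is counted in "any" mode only
  straddle <- list(chrom = "chr1", start = 450, end = 600)
  expect_equal(coverage_in_interval(src, straddle, "any"), 1L)
  expect_equal(coverage_in_interval(src, straddle, "within"), 0L)
  expect_equal(coverage_in_interval(src, list(chrom = "chrX", start = 0, end = 10)), 0L)
})

test_that("SAM ingestion honors MAPQ and CIGAR reference span", {
  sam <- c("@HD\tVN:1.6",
           "r1\t0\tchr1\t101\t42\t100M\t*\t0\t0\t*\t*",
           "r2\t0\tchr1\t201\t5\t100M\t*\t0\t0\t*\t*",     # low MAPQ
           "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",             # unmapped
           "r4\t16\tchr1\t301\t42\t50M10D20M5I25M\t*\t0\t0\t*\t*")
  path <- withr::local_tempfile(lines = sam, fileext = ".sam")
  src <- coverage_from_sam(path, te_config())
  expect_equal(src$n, 2L)
  # r4 spans 50+10+20+25 = 105 reference bases from 0-based 300
  expect_equal(coverage_in_interval(src, list(chrom = "chr1", start = 404, end = 500)), 1L)
  expect_equal(coverage_in_interval(src, list(chrom = "chr1", start = 405, end = 500)), 0L)
})

test_that("local-alignment ratio matches a quadratic oracle on realistic reads", {
  set.seed(77)
  genome <- c(chr1 = random_seq(20000))
  # perfect substring
  expect_equal(local_align_ratio(substr(genome[[1]], 501, 600), genome), 1.0)
  # anchor-only read: 22 genomic nt + 78 random nt
  anchor_read <- paste0(substr(genome[[1]], 1001, 1022), random_seq(78))
  r <- local_align_ratio(anchor_read, genome)
  expect_gte(r, 0.22)
  expect_lte(r, 0.30)
  # zero similarity: poly-A query vs poly-C target
  expect_equal(local_align_ratio(strrep("A", 50), c(x = strrep("C", 500))), 0)
  # agreement with the independent oracle on junction-like and mutated reads
  for (i in 1:12) {
    kind <- i %% 3
    if (kind == 0) {
      p <- sample(19000, 1)
      q <- substr(genome[[1]], p, p + 99)              # pure genome
    } else if (kind == 1) {
      p <- sample(19000, 1)
      cut <- sample(30:70, 1)
      q <- paste0(substr(genome[[1]], p, p + cut - 1), random_seq(100 - cut))
    } else {
      p <- sample(19000, 1)
      q <- substr(genome[[1]], p, p + 99)
      qq <- strsplit(q, "")[[1]]
      at <- sample(100, 6)
      qq[at] <- vapply(qq[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
      q <- paste(qq, collapse = "")                     # degenerate copy read
    }
    if (runif(1) < 0.5) q <- rc(q)
    want <- oracle_local_score(q, genome[[1]]) / nchar(q)
    expect_equal(local_align_ratio(q, genome), want, tolerance = 1e-12)
    expect_equal(local_align_ratio(q, genome, exhaustive = TRUE), want,
                 tolerance = 1e-12)
  }
})
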