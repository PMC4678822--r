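test_that("terminus extraction takes the first and last 22 bases", {
  cfg <- te_config()
  r100 <- random_seq(100)
  t <- extract_termini(r100, cfg)
  expect_equal(t$t5, substr(r100, 1, 22))
  expect_equal(t$t3, substr(r100, 79, 100))
  r45 <- random_seq(45)
  t45 <- extract_termini(r45, cfg)
  expect_equal(nchar(t45$t5) + nchar(t45$t3), 44)   # no shared base
  expect_error(extract_termini(random_seq(44), cfg), class = "read-too-short")
})

test_that("candidate classification requires one unique genome anchor and a TE hit", {
  mk_sum <- function(n_total, target = NA, pos = NA, strand = NA, mm = NA)
    data.frame(n_total = n_total, n_best = pmin(n_total, 1L), target = target,
               pos = pos, strand = strand, mismatches = mm,
               stringsAsFactors = FALSE)
  cfg <- te_config()
  rs <- read_set("r1", strrep("A", 100))
  # t5 unique genome, t3 one TE family -> candidate anchored 5p
  maps <- list(t5_gen = mk_sum(1L, "chr1", 500L, "+", 0L),
               t3_gen = mk_sum(0L),
               t5_te = mk_sum(0L),
               t3_te = mk_sum(1L, "TE01", 10L, "+", 1L))
  got <- classify_insertion_reads(rs, cfg = cfg, maps = maps)
  expect_equal(nrow(got), 1)
  expect_equal(got$anchored_end, "5p")
  expect_equal(got$chrom, "chr1")
  expect_equal(got$anchor_start, 500)
  expect_equal(got$te_family, "TE01")
  # TE side hits too many families -> reject
  maps$t3_te <- mk_sum(6L, "TE01", 10L, "+", 1L)
  expect_equal(nrow(classify_insertion_reads(rs, cfg = cfg, maps = maps)), 0)
  # both termini unique genome -> reject (depletion branch territory)
  maps$t3_te <- mk_sum(1L, "TE01", 10L, "+", 1L)
  maps$t3_gen <- mk_sum(1L, "chr1", 5500L, "+", 0L)
  expect_equal(nrow(classify_insertion_reads(rs, cfg = cfg, maps = maps)), 0)
  # mirrored case anchors at 3p
  maps <- list(t5_gen = mk_sum(0L),
               t3_gen = mk_sum(1L, "chr2", 800L, "-", 1L),
               t5_te = mk_sum(3L, "TE02", 0L, "+", 0L),
               t3_te = mk_sum(0L))
  got <- classify_insertion_reads(rs, cfg = cfg, maps = maps)
  expect_equal(got$anchored_end, "3p")
  expect_equal(got$te_family, "TE02")
})

test_that("score-ratio validation separates genomic artifacts from junction reads", {
  set.seed(42)
  genome <- c(chr1 = random_seq(20000))
  te <- random_seq(2000)   # absent from the genome
  reads <- read_set(
    id = c("artifact", "junction", "anchor_only"),
    seq = c(substr(genome[[1]], 3001, 3100),
            paste0(substr(genome[[1]], 5001, 5050), substr(te, 1, 50)),
            paste0(substr(genome[[1]], 7001, 7022), substr(te, 101, 178))))
  cand <- data.frame(read_id = reads$id, chrom = "chr1",
                     anchor_start = c(3000, 5000, 7000), strand = "+",
                     anchored_end = "5p", te_family = "TE01", te_mm = 0L,
                     blat_ratio = NA_real_, stringsAsFactors = FALSE)
  got <- validate_blat(cand, reads, genome)
  expect_equal(got$blat_ratio[1], 1.0)
  expect_equal(got$blat_ratio[2], 0.5, tolerance = 0.1)
  expect_equal(got$blat_ratio[3], 0.22, tolerance = 0.05)
})

test_that("greedy window clustering matches the peeling oracle and partitions candidates", {
  cfg <- te_config()
  base <- data.frame(read_id = NA, chrom = "chr1", strand = "+",
                     anchored_end = "5p", te_family = "TE01", te_mm = 0L,
                     blat_ratio = 0.3, stringsAsFactors = FALSE)
  mk <- function(pos) {
    d <- base[rep(1, length(pos)), , drop = FALSE]
    d$read_id <- sprintf("r%03d", seq_along(pos))
    d$anchor_start <- pos
    rownames(d) <- NULL
    d
  }
  # worked examples
  cl <- cluster_insertions(mk(c(1000, 1010, 1020, 1030)), cfg)
  expect_equal(nrow(cl), 1); expect_equal(cl$span, 30)
  expect_equal(nrow(cluster_insertions(mk(c(1000, 1400)), cfg)), 2)
  cl3 <- cluster_insertions(mk(c(1000, 1290, 1310)), cfg)
  expect_equal(cl3$read_count, c(2L, 1L))
  # property: equals the oracle over random candidate sets; counts partition
  for (seed in 1:100) {
    set.seed(seed)
    pos <- sample.int(10000, sample(1:100, 1), replace = TRUE)
    got <- cluster_insertions(mk(pos), cfg)
    want_id <- oracle_window_cluster(sort(pos), cfg$cluster_window)
    expect_equal(got$read_count, as.integer(table(want_id)[unique(want_id)]))
    expect_equal(sum(got$read_count), length(pos))
  }
})

test_that("cluster filters implement the read-count, span and ratio rules", {
  cfg <- te_config(read_len = 100)   # span must exceed 100/2 - 22 = 28
  mk_cl <- function(n, span, ratio) {
    cl <- data.frame(chrom = "chr1", start = 1000L, end = 1000L + span + 1L,
                     strand = "+", te_family = "TE01", read_count = n,
                     span = span, mean_blat_ratio = ratio,
                     stringsAsFactors = FALSE)
    attr(cl, "members") <- data.frame()
    cl
  }
  expect_equal(nrow(filter_insertion_clusters(mk_cl(5, 40, 0.5), cfg)), 1)
  expect_equal(nrow(filter_insertion_clusters(mk_cl(4, 20, 0.5), cfg)), 0)
  expect_equal(nrow(filter_insertion_clusters(mk_cl(6, 40, 0.9), cfg)), 0)
  expect_equal(nrow(filter_insertion_clusters(mk_cl(3, 40, 0.5), cfg)), 0)
  # exclusion track removes overlapping clusters
  excl <- data.frame(chrom = "chr1", start = 900, end = 1100)
  expect_equal(nrow(filter_insertion_clusters(mk_cl(5, 40, 0.5), cfg, excl)), 0)
  excl2 <- data.frame(chrom = "chr1", start = 5000, end = 6000)
  expect_equal(nrow(filter_insertion_clusters(mk_cl(5, 40, 0.5), cfg, excl2)), 1)
})

test_that("insertion coverage ratio follows the worked example and is monotone", {
  cfg <- te_config()
  lens <- c(chr1 = 100000L)
  cl <- data.frame(chrom = "chr1", start = 5000L, end = 5150L, strand = "+",
                   te_family = "TE01", read_count = 30L, span = 100L,
                   mean_blat_ratio = 0.4, stringsAsFactors = FALSE)
  cov_n <- function(n) {
    if (n == 0) return(coverage_source(data.frame(chrom = character(0),
                                                  start = integer(0),
                                                  end = integer(0))))
    coverage_source(data.frame(chrom = "chr1", start = seq(5000, by = 5, length.out = n),
                               end = seq(5100, by = 5, length.out = n)))
  }
  # 30 supporting reads over 2 reference reads -> CR = 10
  expect_equal(insertion_cr(cl, cov_n(2), cfg, lens)$cr, 10)
  # pseudocount floor: no reference reads -> CR = read count
  expect_equal(insertion_cr(cl, cov_n(0), cfg, lens)$cr, 30)
  # 4 reads over 7 reference reads -> 0.5
  cl4 <- cl; cl4$read_count <- 4L
  expect_equal(insertion_cr(cl4, cov_n(7), cfg, lens)$cr, 0.5)
  # monotonicity in both directions
  cr_by_cov <- vapply(c(0, 2, 5, 9), function(n) insertion_cr(cl, cov_n(n), cfg, lens)$cr, 0)
  expect_true(all(diff(cr_by_cov) < 0))
  cl_more <- cl; cl_more$read_count <- 31L
  expect_gt(insertion_cr(cl_more, cov_n(2), cfg, lens)$cr,
            insertion_cr(cl, cov_n(2), cfg, lens)$cr)
  # the window is expanded by 22 nt at its 5' coordinate before counting
  edge <- coverage_source(data.frame(chrom = "chr1", start = 4940, end = 4979))
  expect_equal(insertion_cr(cl, edge, cfg, lens)$ref_reads, 1L)  # 4978 >= 5000-22
  edge2 <- coverage_source(data.frame(chrom = "chr1", start = 4940, end = 4978))
  expect_equal(insertion_cr(cl, edge2, cfg, lens)$ref_reads, 0L)
})
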