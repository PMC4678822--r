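mk_dep_sum <- function(n_total, target = NA, pos = NA, strand = NA, mm = 0L)
  data.frame(n_total = n_total, n_best = pmin(n_total, 1L), target = target,
             pos = pos, strand = strand, mismatches = mm,
             stringsAsFactors = FALSE)

test_that("depletion classification needs unique concordant distant termini", {
  cfg <- te_config(read_len = 100)
  rs <- read_set("r1", strrep("A", 100))
  # termini 5000 nt apart, same chrom/strand -> candidate with the right gap
  maps <- list(t5 = mk_dep_sum(1L, "chr1", 1000L, "+"),
               t3 = mk_dep_sum(1L, "chr1", 6022L, "+"))
  got <- classify_depletion_reads(rs, cfg = cfg, maps = maps)
  expect_equal(nrow(got), 1)
  expect_equal(got$gap, 5000)
  expect_equal(got$left_end, 1022)
  # ordinary read spacing -> reject
  maps$t3 <- mk_dep_sum(1L, "chr1", 1102L, "+")
  expect_equal(nrow(classify_depletion_reads(rs, cfg = cfg, maps = maps)), 0)
  # different chromosomes -> reject
  maps$t3 <- mk_dep_sum(1L, "chr2", 6022L, "+")
  expect_equal(nrow(classify_depletion_reads(rs, cfg = cfg, maps = maps)), 0)
  # discordant strands -> reject
  maps$t3 <- mk_dep_sum(1L, "chr1", 6022L, "-")
  expect_equal(nrow(classify_depletion_reads(rs, cfg = cfg, maps = maps)), 0)
  # non-unique terminus -> reject
  maps$t3 <- mk_dep_sum(3L, "chr1", 6022L, "+")
  expect_equal(nrow(classify_depletion_reads(rs, cfg = cfg, maps = maps)), 0)
  # minus-strand read: termini arrive right-to-left but normalize the same way
  maps <- list(t5 = mk_dep_sum(1L, "chr1", 6022L, "-"),
               t3 = mk_dep_sum(1L, "chr1", 1000L, "-"))
  got <- classify_depletion_reads(rs, cfg = cfg, maps = maps)
  expect_equal(got$gap, 5000)
  expect_equal(got$left_start, 1000)
})

test_that("two-sided clustering matches its oracle and applies the read floor", {
  cfg <- te_config()
  mk <- function(left, right, strand = "+") {
    data.frame(read_id = sprintf("r%03d", seq_along(left)), chrom = "chr1",
               strand = strand, left_start = left, left_end = left + 22L,
               right_start = right, gap = right - left - 22L,
               stringsAsFactors = FALSE)
  }
  # 4 candidates bracketing one excision -> 1 cluster with innermost sides
  cand <- mk(c(1000, 1010, 1030, 1050), c(3000, 3010, 3035, 3060))
  got <- cluster_depletions(cand, cfg)
  expect_equal(nrow(got), 1)
  expect_equal(got$five_end, 1072)      # max left_end
  expect_equal(got$three_start, 3000)   # min right_start
  # 3 candidates fall below the 4-read floor
  expect_equal(nrow(cluster_depletions(mk(c(1, 2, 3), c(9000, 9001, 9002)), cfg)), 0)
  # two excisions 10 kb apart, 5 candidates each -> 2 clusters
  cand2 <- rbind(mk(seq(1000, 1080, 20), seq(3000, 3080, 20)),
                 mk(seq(11000, 11080, 20), seq(13000, 13080, 20)))
  cand2$read_id <- sprintf("r%03d", seq_len(nrow(cand2)))
  expect_equal(nrow(cluster_depletions(cand2, cfg)), 2)
  # property: member assignment equals the transparent restatement
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(1:100, 1)
    # rights sit comfortably beyond the joint window so every raw group is
    # a valid cluster (five_end < three_start) and the partition is total
    left <- sample.int(20000, n, replace = TRUE)
    right <- left + 1000 + sample.int(5000, n, replace = TRUE)
    cand <- mk(left, right)
    cfg0 <- te_config(min_cluster_reads = 1L)   # compare raw partitions
    got <- cluster_depletions(cand, cfg0)
    want_id <- oracle_depletion_cluster(left, right, cfg$cluster_window)
    expect_equal(nrow(got), length(unique(want_id)))
    expect_equal(sum(got$read_count), n)
    mem <- attr(got, "members")
    # same partition: members grouped identically (compare co-membership sizes)
    expect_equal(sort(as.integer(table(mem$cluster))),
                 sort(as.integer(table(want_id))))
  }
})

test_that("flank intervals follow the printed arithmetic and clamp at edges", {
  cfg <- te_config(read_len = 100)
  fl <- depletion_flank_intervals(list(chrom = "chr1", five_end = 10000,
                                       three_start = 15000), cfg, 1e6)
  expect_equal(c(fl$iv5$start, fl$iv5$end), c(9960, 10042))
  expect_equal(c(fl$iv3$start, fl$iv3$end), c(14980, 15020))
  # left clamp at the chromosome start
  fl2 <- depletion_flank_intervals(list(chrom = "chr1", five_end = 10,
                                        three_start = 15000), cfg, 1e6)
  expect_equal(fl2$iv5$start, 0)
  # fractional bounds round half away from zero for L not divisible by 5
  cfg2 <- te_config(read_len = 101)
  fl3 <- depletion_flank_intervals(list(chrom = "chr1", five_end = 1000,
                                        three_start = 2000), cfg2, 1e6)
  expect_equal(c(fl3$iv5$start, fl3$iv5$end), c(1000 - 40, 1000 + 22 + 20))
})

test_that("depletion coverage ratio averages the two flanks over a pseudocount", {
  cfg <- te_config(read_len = 100)
  lens <- c(chr1 = 1e6)
  cl <- data.frame(chrom = "chr1", five_end = 10000L, three_start = 15000L,
                   strand = ".", read_count = 10L, stringsAsFactors = FALSE)
  cov_for <- function(n5, n3) {
    rows <- rbind(
      if (n5) data.frame(chrom = "chr1", start = seq(9990, by = 2, length.out = n5),
                         end = seq(10030, by = 2, length.out = n5)),
      if (n3) data.frame(chrom = "chr1", start = seq(14990, by = 2, length.out = n3),
                         end = seq(15010, by = 2, length.out = n3)))
    if (is.null(rows)) rows <- data.frame(chrom = character(0), start = integer(0),
                                          end = integer(0))
    coverage_source(rows)
  }
  expect_equal(depletion_cr(cl, cov_for(4, 4), cfg, lens)$cr, 2.0)
  cl8 <- cl; cl8$read_count <- 8L
  expect_equal(depletion_cr(cl8, cov_for(0, 0), cfg, lens)$cr, 8)
  cl6 <- cl; cl6$read_count <- 6L
  expect_equal(depletion_cr(cl6, cov_for(3, 5), cfg, lens)$cr, 1.2)
})

test_that("only TE-spanning depletions are kept, named by the nearest-midpoint copy", {
  rm <- data.frame(chrom = "chr1",
                   start = c(2000, 5000, 6100), end = c(3000, 6000, 6600),
                   name = c("roo", "copia", "blood"), stringsAsFactors = FALSE)
  cl <- data.frame(chrom = "chr1",
                   five_end = c(1900, 8000, 4900),
                   three_start = c(3100, 8200, 6700),
                   strand = ".", read_count = 5L, stringsAsFactors = FALSE)
  got <- keep_te_depletions(cl, rm)
  expect_equal(nrow(got), 2)
  expect_equal(got$te_name[1], "roo")
  # span [4900, 6700): midpoint 5800; copia mid 5500 (d=300), blood mid 6350 (d=550)
  expect_equal(got$te_name[2], "copia")
})
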