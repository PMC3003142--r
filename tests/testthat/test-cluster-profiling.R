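mk_aln <- function(chrom, start, width, strand, id) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width),
                         strand = strand, read_id = id,
                         n_hits = rep(1L, length(start)))
}

test_that("cluster_histogram normalizes to reads per million depth", {
  ann <- annotation_set("chr4:1001-4000")
  aln <- mk_aln("chr4", seq(1100, by = 50, length.out = 10), 25, "-",
                paste0("r", 1:10))
  h <- cluster_histogram(aln, ann, depth = 1e6)
  expect_equal(h$normalized["-", "25"], 10.0)
  expect_equal(h$raw["-", "25"], 10L)
  expect_equal(sum(h$raw), 10L)
  # zero cluster reads -> all bins zero
  far <- mk_aln("chr4", 5000, 25, "+", "q1")
  h0 <- cluster_histogram(far, ann, depth = 100)
  expect_true(all(h0$raw == 0))
  expect_error(cluster_histogram(aln, ann, depth = 0), "depth")
})

test_that("histogram conservation: raw sums equal cluster reads, constant ratio", {
  g <- generate_genome(demo_genome_spec(seed = 12))
  lib <- generate_library(g$genome, g$annotations,
                          wt_library_spec(n_reads = 20000, seed = 13))
  pr <- profile_library(lib$reads, g$genome, g$annotations, genotype = "wt")
  h <- pr$histogram
  expect_equal(sum(h$raw), h$n_cluster_reads)
  nz <- h$raw > 0
  expect_equal(as.numeric(h$normalized[nz] / h$raw[nz]),
               rep(1e6 / h$depth, sum(nz)))
  # cluster reads are a subset of depth-counted reads
  expect_lte(h$n_cluster_reads, h$depth)
})

test_that("a multi-strand multi-mapper is assigned to its leftmost cluster placement", {
  ann <- annotation_set("chr4:1001-4000")
  aln <- GenomicRanges::GRanges(
    "chr4", IRanges::IRanges(c(2001, 1501), width = 25), strand = c("+", "-"),
    read_id = c("r1", "r1"), n_hits = c(2L, 2L))
  h <- cluster_histogram(aln, ann, depth = 100)
  expect_equal(sum(h$raw), 1L)
  expect_equal(h$raw["-", "25"], 1L)  # leftmost placement is the minus one
  expect_equal(h$n_strand_ambiguous, 1L)
})

test_that("wt library histogram matches planted class structure", {
  g <- generate_genome(demo_genome_spec(seed = 12))
  spec <- wt_library_spec(n_reads = 50000, seed = 14)
  lib <- generate_library(g$genome, g$annotations, spec)
  pr <- profile_library(lib$reads, g$genome, g$annotations, genotype = "wt")
  h <- pr$histogram
  # the 21 nt endo-siRNA peak sits on the minus strand and towers over
  # neighbouring short minus bins
  expect_gt(h$raw["-", "21"], h$raw["-", "20"])
  expect_gt(h$raw["-", "21"], h$raw["-", "22"])
  # per-class ground-truth counts within binomial 99% bounds of the histogram
  truth <- lib$truth
  n_endo <- sum(truth$class == "endo_sirna_21")
  expect_true(within_binomial_99(h$raw["-", "21"] / spec$n_reads,
                                 spec$class_weights[["endo_sirna_21"]],
                                 spec$n_reads))
  short_raw <- sum(h$raw["-", c("19", "20", "22")])
  expect_true(within_binomial_99(short_raw / spec$n_reads,
                                 spec$class_weights[["short_minus_19_22"]],
                                 spec$n_reads))
  # strand split: plus cluster reads come from the plus piRNA class
  plus_raw <- sum(h$raw["+", as.character(23:29)])
  expect_true(within_binomial_99(plus_raw / spec$n_reads,
                                 spec$class_weights[["pirna_plus_23_29"]],
                                 spec$n_reads))
})

test_that("size classes sum exactly {19,20,22} and 23-29, never length 21", {
  ann <- annotation_set("chr4:1001-4000")
  starts <- seq(1100, by = 20, length.out = 115)
  lens <- rep(c(19, 20, 21, 22), c(5, 5, 100, 5))
  aln <- mk_aln("chr4", starts, lens, "-", paste0("r", seq_along(starts)))
  h <- cluster_histogram(aln, ann, depth = 1e6)
  sc <- size_class_summary(h, genotype = "x")
  expect_equal(sc$abundance[sc$size_class == "short_19_22_excl21" &
                              sc$strand == "-"], 15.0)
  # structural exclusion of the 21 nt bin: doubling it changes nothing
  h2 <- h
  h2$raw["-", "21"] <- h2$raw["-", "21"] * 2L
  h2$normalized["-", "21"] <- h2$normalized["-", "21"] * 2
  expect_equal(size_class_summary(h2)$abundance, sc$abundance)

  # all-zero histogram -> all classes zero
  h0 <- cluster_histogram(GenomicRanges::GRanges(), ann, depth = 10)
  expect_true(all(size_class_summary(h0)$abundance == 0))

  # random histogram equals brute-force sums over the stated length sets
  set.seed(99)
  n <- 400
  aln_r <- mk_aln("chr4", sample(1100:3800, n, TRUE), sample(18:30, n, TRUE),
                  sample(c("+", "-"), n, TRUE), paste0("q", 1:n))
  hr <- cluster_histogram(aln_r, ann, depth = 12345)
  scr <- size_class_summary(hr)
  for (st in c("+", "-")) {
    expect_equal(scr$abundance[scr$size_class == "short_19_22_excl21" &
                                 scr$strand == st],
                 sum(hr$normalized[st, c("19", "20", "22")]))
    expect_equal(scr$abundance[scr$size_class == "long_23_29" &
                                 scr$strand == st],
                 sum(hr$normalized[st, as.character(23:29)]))
  }
})

test_that("fold_change divides mutant by wt and flags undefined ratios", {
  mk_sc <- function(vals, genotype) {
    out <- data.frame(genotype = genotype,
                      size_class = rep(c("short_19_22_excl21", "long_23_29"),
                                       each = 2),
                      strand = rep(c("+", "-"), 2), abundance = vals,
                      stringsAsFactors = FALSE)
    class(out) <- c("size_class_summary", "data.frame")
    out
  }
  wt <- mk_sc(c(10, 20, 30, 40), "wt")
  mut <- mk_sc(c(10, 4, 30, 40), "mut")
  fc <- fold_change(mut, wt)
  expect_equal(fc$ratio[fc$size_class == "short_19_22_excl21" &
                          fc$strand == "-"], 0.2)
  # identity
  expect_true(all(fold_change(wt, wt)$ratio == 1))
  # wt zero -> flagged undefined, not dropped
  wt0 <- mk_sc(c(0, 20, 30, 40), "wt")
  fc0 <- fold_change(mut, wt0)
  expect_equal(nrow(fc0), 4L)
  row <- fc0[fc0$strand == "+" & fc0$size_class == "short_19_22_excl21", ]
  expect_true(row$undefined)
  expect_true(is.na(row$ratio))
  # mismatched class sets -> error
  bad <- wt[-1, ]
  class(bad) <- class(wt)
  expect_error(fold_change(mut, bad), "mismatched")
})

test_that("cluster_attribution is the in-cluster share of telomeric reads", {
  ann <- annotation_set(
    "chr4:1001-4000",
    elements = GenomicRanges::GRanges(c("chr4", "chrX"),
                                      IRanges::IRanges(c(1201, 501), c(1800, 1100)),
                                      strand = "-", name = c("in", "out")))
  # all telomeric placements inside the cluster -> fraction 1
  aln <- mk_aln("chr4", seq(1210, by = 25, length.out = 8), 24, "-",
                paste0("r", 1:8))
  expect_equal(cluster_attribution(aln, ann)$fraction, 1.0)
  # 2 of 8 telomeric reads only hit the off-cluster fragment -> 0.75
  aln2 <- mk_aln(rep(c("chr4", "chrX"), c(6, 2)),
                 c(seq(1210, by = 25, length.out = 6), 520, 700), 24, "-",
                 paste0("r", 1:8))
  att <- cluster_attribution(aln2, ann)
  expect_equal(att$fraction, 0.75)
  expect_equal(att$n_telomeric, 8L)
  # no telomeric reads -> undefined, flagged
  att0 <- cluster_attribution(mk_aln("chr4", 3500, 24, "+", "r1"), ann)
  expect_true(att0$undefined)
  expect_true(is.na(att0$fraction))
})

test_that("ping-pong overlap follows the 5'-to-5' inclusive convention", {
  # plus read at 1-based [101,125], minus read [92,116]: minus 5' end is 116,
  # overlap = 116 - 101 + 1 = 16
  aln <- GenomicRanges::GRanges(
    "chr4", IRanges::IRanges(c(101, 92), c(125, 116)), strand = c("+", "-"),
    read_id = c("p", "m"), n_hits = c(1L, 1L))
  pp <- ping_pong_signature(aln)
  expect_equal(unname(pp$counts[["16"]]), 1)
  expect_equal(pp$n_pairs, 1)
  # opposite chromosomes contribute to no bin
  aln2 <- GenomicRanges::GRanges(
    c("chr4", "chrX"), IRanges::IRanges(c(101, 92), c(125, 116)),
    strand = c("+", "-"), read_id = c("p", "m"), n_hits = c(1L, 1L))
  expect_equal(ping_pong_signature(aln2)$n_pairs, 0)
})

test_that("ping-pong histogram agrees with the O(n^2) pair oracle", {
  set.seed(202)
  n <- 400
  aln <- GenomicRanges::GRanges(
    sample(c("chr4", "chrX"), n, TRUE),
    IRanges::IRanges(sample(1000:1200, n, TRUE), width = sample(19:29, n, TRUE)),
    strand = sample(c("+", "-"), n, TRUE),
    read_id = paste0("r", 1:n), n_hits = rep(1L, n))
  pp <- ping_pong_signature(aln)
  expect_equal(unname(pp$counts), unname(oracle_pingpong(aln_as_df(aln))))
})

test_that("planted 10 nt overlap pairs produce a modal 10 nt bin", {
  g <- generate_genome(demo_genome_spec(seed = 31))
  spec <- library_spec("pp", 4000,
                       c(pirna_minus_23_29 = 0.5, pirna_plus_23_29 = 0.5),
                       pingpong = list(n_pairs = 1500, overlap = 10),
                       seed = 32)
  lib <- generate_library(g$genome, g$annotations, spec)
  pr <- profile_library(lib$reads, g$genome, g$annotations, genotype = "pp")
  pp <- ping_pong_signature(pr$alignments, region = g$annotations$cluster)
  expect_equal(pp$modal, 10L)
  expect_gt(pp$z10, 3)
})
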