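test_that("map_inserts reports every exact placement on both strands", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  mr <- map_inserts(c(r1 = "CGTA"), g)
  aln <- mr$alignments
  # full both-strand truth (confirmed by the brute-force oracle): plus hits at
  # 1-based 2 and 6, and revcomp TACG on the minus strand at 4-7
  expected <- oracle_map_one("CGTA", c(chr1 = "ACGTACGTAC"))
  expect_equal(length(aln), nrow(expected))
  expect_setequal(paste(BiocGenerics::start(aln),
                        as.character(BiocGenerics::strand(aln))),
                  paste(expected$start, expected$strand))
  expect_setequal(BiocGenerics::start(aln[BiocGenerics::strand(aln) == "+"]),
                  c(2L, 6L))  # 0-based starts 1 and 5
  expect_true(all(aln$n_hits == nrow(expected)))

  # minus-strand: insert equal to revcomp of genome[3..8] (1-based), unique
  g2 <- Biostrings::DNAStringSet(c(chr1 = "AAACCCTTTGGGAAA"))
  ins <- oracle_revcomp(substr(as.character(g2[[1]]), 3, 8))
  mr2 <- map_inserts(stats::setNames(ins, "r1"), g2)
  aln2 <- mr2$alignments
  expect_equal(as.character(BiocGenerics::strand(aln2)), "-")
  expect_equal(BiocGenerics::start(aln2), 3L)
  expect_equal(BiocGenerics::end(aln2), 8L)

  # absent insert: unmapped
  g3 <- Biostrings::DNAStringSet(c(chr1 = "ACACACACAC"))
  mr3 <- map_inserts(c(r1 = "TTTTT", r2 = "ACACA"), g3)
  expect_equal(mr3$unmapped, "r1")
  expect_error(map_inserts(c(r1 = "ACGT"), Biostrings::DNAStringSet()), "empty genome")
})

test_that("map_inserts equals a brute-force both-strand substring scan", {
  set.seed(55)
  gch <- c(chrA = random_seq(3000), chrB = random_seq(1500))
  genome <- Biostrings::DNAStringSet(gch)
  # a mix of planted substrings (some revcomped), random inserts, and an N case
  ins <- character(0)
  for (i in 1:60) {
    L <- sample(6:25, 1)
    chrom <- sample(names(gch), 1)
    s <- sample(nchar(gch[[chrom]]) - L, 1)
    x <- substr(gch[[chrom]], s, s + L - 1)
    if (i %% 2 == 0) x <- oracle_revcomp(x)
    ins <- c(ins, x)
  }
  ins <- c(ins, replicate(40, random_seq(sample(4:12, 1))),
           "ACGNNTA")
  names(ins) <- paste0("r", seq_along(ins))
  mr <- map_inserts(ins, genome)

  for (id in names(ins)) {
    expected <- oracle_map_one(ins[[id]], gch)
    got <- mr$alignments[mr$alignments$read_id == id]
    expect_equal(length(got), nrow(expected), info = id)
    if (nrow(expected)) {
      key <- function(ch, s, st) sort(paste(ch, s, st))
      expect_equal(key(as.character(GenomeInfoDb::seqnames(got)),
                       BiocGenerics::start(got),
                       as.character(BiocGenerics::strand(got))),
                   key(expected$chrom, expected$start, expected$strand),
                   info = id)
      expect_true(all(got$n_hits == nrow(expected)))
    } else {
      expect_true(id %in% mr$unmapped, info = id)
    }
  }
})

test_that("mapping is reverse-complement symmetric", {
  set.seed(77)
  gch <- c(chr1 = random_seq(2000))
  genome <- Biostrings::DNAStringSet(gch)
  for (i in 1:20) {
    L <- sample(8:20, 1)
    s <- sample(2000 - L, 1)
    x <- substr(gch[["chr1"]], s, s + L - 1)
    a <- map_inserts(stats::setNames(x, "f"), genome)$alignments
    b <- map_inserts(stats::setNames(oracle_revcomp(x), "r"), genome)$alignments
    expect_equal(length(a), length(b))
    flip <- c("+" = "-", "-" = "+")
    expect_setequal(paste(BiocGenerics::start(a), BiocGenerics::end(a),
                          flip[as.character(BiocGenerics::strand(a))]),
                    paste(BiocGenerics::start(b), BiocGenerics::end(b),
                          as.character(BiocGenerics::strand(b))))
  }
})

test_that("chromosome blocklist and multi-hit cap behave like aligner options", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC", chrY = "ACGTACGTAC"))
  mr <- map_inserts(c(r1 = "CGTA"), g, blocklist = "chrY")
  expect_true(all(as.character(GenomeInfoDb::seqnames(mr$alignments)) == "chr1"))
  mr2 <- map_inserts(c(r1 = "CGTA"), g, max_hits = 2)
  expect_equal(mr2$suppressed, "r1")
  expect_equal(length(mr2$alignments), 0L)
})

test_that("filter_ncrna removes whole reads by any >=1 nt overlap, strand-agnostic", {
  ann <- annotation_set("chr1:1-100",
                        ncrna = GenomicRanges::GRanges("chr1",
                                                       IRanges::IRanges(50, 60)))
  aln <- GenomicRanges::GRanges(
    rep("chr1", 4), IRanges::IRanges(c(55, 200, 30, 61), c(70, 220, 45, 80)),
    strand = c("-", "+", "+", "+"),
    read_id = c("a", "a", "b", "c"), n_hits = c(2L, 2L, 1L, 1L))
  fl <- filter_ncrna(aln, ann)
  # read a: one placement overlaps (on the minus strand) -> both placements go
  expect_equal(fl$removed, "a")
  expect_setequal(fl$alignments$read_id, c("b", "c"))
  # read c abuts the interval end (starts at 61, interval ends 60): kept
  expect_true("c" %in% fl$alignments$read_id)
})

test_that("filter_ncrna never removes reads with zero overlap (O(nm) oracle)", {
  set.seed(13)
  n <- 300
  aln <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), n, TRUE),
    IRanges::IRanges(sample(1:5000, n, TRUE), width = sample(18:29, n, TRUE)),
    strand = sample(c("+", "-"), n, TRUE),
    read_id = paste0("r", sample(1:150, n, TRUE)), n_hits = 1L)
  iv <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 12, TRUE),
                               IRanges::IRanges(sample(1:5000, 12, TRUE),
                                                width = sample(50:300, 12, TRUE)))
  ann <- annotation_set("chr1:1-10", ncrna = iv)
  fl <- filter_ncrna(aln, ann)
  expected_bad <- oracle_overlapping_reads(
    aln_as_df(aln),
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(iv)),
               start = BiocGenerics::start(iv), end = BiocGenerics::end(iv)))
  expect_setequal(fl$removed, expected_bad)
  expect_setequal(unique(aln$read_id[!aln$read_id %in% expected_bad]),
                  unique(fl$alignments$read_id))
})

test_that("mapped_depth counts distinct reads, not alignments", {
  aln <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(rep(1, 8), width = 20), strand = "+",
    read_id = rep(c("a", "b", "c"), c(1, 2, 5)), n_hits = rep(c(1L, 2L, 5L), c(1, 2, 5)))
  expect_equal(mapped_depth(aln), 3L)
  expect_equal(mapped_depth(GenomicRanges::GRanges()), 0L)
})

test_that("depth on a synthetic library equals ground-truth mappable non-ncRNA reads", {
  g <- tiny_fixture(seed = 21)
  spec <- library_spec("d", 4000,
                       c(pirna_minus_23_29 = 0.5, pirna_plus_23_29 = 0.2,
                         background_offcluster = 0.2, unmatched_junk = 0.1),
                       seed = 3)
  lib <- generate_library(g$genome, g$annotations, spec)
  lf <- length_filter(trim_linker(lib$reads, spec$linker), 18, 30)
  mr <- map_inserts(lf$inserts, g$genome)
  fl <- filter_ncrna(mr, g$annotations)
  depth <- mapped_depth(fl$alignments)
  # from ground truth: non-junk reads that kept full length and avoid ncRNA
  sixmer <- substr(spec$linker, 1, 6)
  truth <- lib$truth
  intact <- truth$class != "unmatched_junk" &
    !grepl(sixmer, substr(lib$reads[truth$read_id], 1, truth$insert_length),
           fixed = TRUE)
  nc <- g$annotations$ncrna
  ovl <- rep(FALSE, nrow(truth))
  ok <- !is.na(truth$chrom)
  ovl[ok] <- truth$chrom[ok] == as.character(GenomeInfoDb::seqnames(nc))[1] &
    truth$start[ok] <= BiocGenerics::end(nc)[1] &
    truth$end[ok] >= BiocGenerics::start(nc)[1]
  expected_ids <- truth$read_id[intact & !ovl]
  got_ids <- unique(fl$alignments$read_id)
  # reads whose insert was truncated by a chance internal 6-mer may drop out or
  # remap; everything else must agree exactly
  expect_setequal(setdiff(expected_ids, got_ids), character(0))
  extra <- setdiff(got_ids, expected_ids)
  expect_lt(length(extra) / nrow(truth), 0.02)
  expect_equal(depth, length(got_ids))
})

test_that("alignment TSV round-trips through 0-based half-open disk format", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  mr <- map_inserts(c(r1 = "CGTA"), g)
  path <- tempfile(fileext = ".tsv")
  write_alignments(mr, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(sort(tab$start0), c(1L, 3L, 5L))
  back <- read_alignments(path)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(mr$alignments))
  expect_equal(back$read_id, mr$alignments$read_id)
})
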