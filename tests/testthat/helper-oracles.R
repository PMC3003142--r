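# Independent brute-force oracles and small fixtures shared across tests.
# Oracles deliberately avoid the code paths they check: plain character
# scanning and O(n^2) pair enumeration only.

ORACLE_BASES <- c("A", "C", "G", "T")

random_seq <- function(n, bases = ORACLE_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Leftmost position (1-based) where the 6-mer occurs in read, scanning every
# offset and comparing substrings; 0 if absent.
oracle_first_sixmer <- function(read, sixmer) {
  read <- toupper(read)
  n <- nchar(read)
  if (n < 6) return(0L)
  for (k in seq_len(n - 5)) {
    if (substr(read, k, k + 5) == sixmer) return(k)
  }
  0L
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All exact full-length placements of insert on both strands of a genome
# given as a named character vector; returns data.frame(chrom, start, end,
# strand), 1-based inclusive.
oracle_map_one <- function(insert, genome_chars) {
  insert <- toupper(insert)
  rc <- oracle_revcomp(insert)
  out <- list()
  for (chrom in names(genome_chars)) {
    g <- genome_chars[[chrom]]
    L <- nchar(insert)
    for (pat_strand in list(c(insert, "+"), c(rc, "-"))) {
      pos <- integer(0)
      from <- 1L
      repeat {
        k <- regexpr(pat_strand[1], substr(g, from, nchar(g)), fixed = TRUE)
        if (k < 0) break
        pos <- c(pos, from + k - 1L)
        from <- from + k  # step one base forward to catch overlapping hits
      }
      if (length(pos))
        out[[length(out) + 1]] <- data.frame(chrom = chrom, start = pos,
                                             end = pos + L - 1L,
                                             strand = pat_strand[2])
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), strand = character(0)))
  do.call(rbind, out)
}

# O(n * m) interval-overlap check: ids of alignments overlapping any interval
# by >= 1 nt (1-based closed coordinates), strand-agnostic.
oracle_overlapping_reads <- function(aln_df, intervals_df) {
  bad <- character(0)
  for (i in seq_len(nrow(aln_df))) {
    for (j in seq_len(nrow(intervals_df))) {
      if (aln_df$chrom[i] == intervals_df$chrom[j] &&
          aln_df$start[i] <= intervals_df$end[j] &&
          aln_df$end[i] >= intervals_df$start[j]) {
        bad <- c(bad, aln_df$read_id[i])
        break
      }
    }
  }
  unique(bad)
}

# O(n^2) ping-pong pair enumeration over a data.frame(chrom, start, end,
# strand); counts pairs by 5'-to-5' overlap d = minus_end - plus_start + 1.
oracle_pingpong <- function(df, max_overlap = 30) {
  counts <- stats::setNames(numeric(max_overlap), seq_len(max_overlap))
  plus <- df[df$strand == "+", ]
  minus <- df[df$strand == "-", ]
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$chrom[i] != minus$chrom[j]) next
      d <- minus$end[j] - plus$start[i] + 1
      if (d >= 1 && d <= max_overlap) counts[d] <- counts[d] + 1
    }
  }
  counts
}

aln_as_df <- function(gr) {
  data.frame(read_id = gr$read_id, chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

# Two-sided 99% binomial sampling check: is phat consistent with p at n draws?
within_binomial_99 <- function(phat, p, n) {
  abs(phat - p) <= stats::qnorm(0.995) * sqrt(p * (1 - p) / n) + 1e-12
}

# Small deterministic genome + annotations used across mapping/profiling tests.
tiny_fixture <- function(seed = 11) {
  gs <- genome_spec(
    c(chrA = 5000L, chrB = 3000L), "chrA:1001-4000",
    elements = GenomicRanges::GRanges(
      c("chrA", "chrA", "chrB"),
      IRanges::IRanges(c(1201, 2501, 501), c(1800, 3600, 1100)),
      strand = "-", name = c("HeT-A_a", "TART_a", "HeT-A_b")),
    ncrna = GenomicRanges::GRanges("chrA", IRanges::IRanges(4501, 4600),
                                   name = "ncRNA_t"),
    seed = seed)
  generate_genome(gs)
}
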