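#' Map inserts to a genome by exact full-length matching on both strands
#'
#' Reports every perfect full-length placement of each insert on the plus
#' strand (insert equals the genomic substring) and the minus strand (insert
#' equals its reverse complement), with zero mismatches — the full-match
#' convention of exact short-read alignment. Multi-mappers are retained with
#' all placements and `n_hits` recorded on every alignment; a configurable
#' cap (default unlimited) suppresses reads whose placement count exceeds it,
#' in the style of an aligner's `-m` limit. Inserts with no placement (or
#' containing non-ACGT bases, which can never match) are counted as unmapped.
#'
#' @param inserts Named character vector of insert sequences (length-filtered).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param blocklist Chromosome names excluded before mapping (e.g. a
#'   heterochromatic scaffold to leave out of a female genome build).
#' @param max_hits Suppress reads with more than this many placements.
#' @return A `mapping_result` list: `alignments` (a
#'   [GenomicRanges::GRanges], 1-based closed intervals, with `read_id` and
#'   `n_hits` metadata), `unmapped` and `suppressed` read-id vectors, and
#'   `n_input`.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
#' map_inserts(c(r1 = "CGTA"), g)$alignments
map_inserts <- function(inserts, genome, blocklist = character(0), max_hits = Inf) {
  stopifnot(is.character(inserts))
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    stop("empty genome")
  if (is.null(names(genome))) stop("genome chromosomes must be named")
  genome <- genome[setdiff(names(genome), blocklist)]
  if (length(genome) == 0) stop("blocklist removed every chromosome")
  if (is.null(names(inserts))) names(inserts) <- paste0("insert_", seq_along(inserts))
  ids <- names(inserts)
  seqs <- toupper(inserts)

  uniq <- unique(seqs)
  uidx <- match(seqs, uniq)
  clean <- grepl("^[ACGT]+$", uniq)

  hit_u <- integer(0); hit_chrom <- character(0)
  hit_start <- integer(0); hit_width <- integer(0); hit_strand <- character(0)
  for (w in unique(nchar(uniq[clean]))) {
    sub <- which(clean & nchar(uniq) == w)
    pats <- Biostrings::DNAStringSet(uniq[sub])
    pd_plus <- Biostrings::PDict(pats)
    pd_minus <- Biostrings::PDict(Biostrings::reverseComplement(pats))
    for (chrom in names(genome)) {
      if (Biostrings::width(genome[chrom]) < w) next
      for (strand_sym in c("+", "-")) {
        pd <- if (strand_sym == "+") pd_plus else pd_minus
        m <- Biostrings::matchPDict(pd, genome[[chrom]])
        cnt <- S4Vectors::elementNROWS(m)
        if (sum(cnt) == 0) next
        st <- start(unlist(m))
        hit_u <- c(hit_u, rep(sub, cnt))
        hit_chrom <- c(hit_chrom, rep(chrom, sum(cnt)))
        hit_start <- c(hit_start, st)
        hit_width <- c(hit_width, rep(w, sum(cnt)))
        hit_strand <- c(hit_strand, rep(strand_sym, sum(cnt)))
      }
    }
  }

  n_hits_u <- tabulate(hit_u, nbins = length(uniq))
  unmapped_u <- which(n_hits_u == 0)
  suppressed_u <- which(n_hits_u > max_hits)
  keep_u <- n_hits_u >= 1 & n_hits_u <= max_hits

  unmapped <- ids[uidx %in% unmapped_u]
  suppressed <- ids[uidx %in% suppressed_u]

  keep_hit <- keep_u[hit_u]
  hits_by_u <- split(which(keep_hit), factor(hit_u[keep_hit], levels = seq_along(uniq)))
  mapped_read <- which(keep_u[uidx])
  rows_list <- hits_by_u[uidx[mapped_read]]
  n_per_read <- lengths(rows_list)
  rows <- unlist(rows_list, use.names = FALSE)
  read_id <- rep(ids[mapped_read], n_per_read)

  aln <- GRanges(hit_chrom[rows],
                 IRanges(hit_start[rows], width = hit_width[rows]),
                 strand = hit_strand[rows],
                 read_id = read_id,
                 n_hits = n_hits_u[hit_u[rows]],
                 seqinfo = GenomeInfoDb::Seqinfo(names(genome),
                                                 Biostrings::width(genome)))
  structure(list(alignments = aln, unmapped = unmapped, suppressed = suppressed,
                 n_input = length(ids)),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf(
    "mapping_result: %d inserts in, %d mapped (%d alignments), %d unmapped, %d suppressed\n",
    x$n_input, length(unique(x$alignments$read_id)), length(x$alignments),
    length(x$unmapped), length(x$suppressed)))
  invisible(x)
}

as_alignments <- function(x) {
  if (inherits(x, "mapping_result")) x$alignments else x
}

#' Remove reads attributable to ncRNAs or pre-miRNAs
#'
#' A read is removed — with all of its alignments — if any of its placements
#' overlaps any ncRNA/pre-miRNA interval by at least 1 nt, regardless of
#' strand. Removal is by read, not by placement: the sequence is judged to be
#' an ncRNA fragment, so none of its placements may be counted anywhere.
#'
#' @param alignments A `mapping_result` or alignment `GRanges`.
#' @param annotations An [annotation_set] whose `ncrna` track defines the
#'   intervals.
#' @return List with `alignments` (surviving `GRanges`) and `removed`
#'   (read ids dropped).
#' @export
filter_ncrna <- function(alignments, annotations) {
  aln <- as_alignments(alignments)
  stopifnot(inherits(annotations, "annotation_set"))
  if (length(annotations$ncrna) == 0 || length(aln) == 0)
    return(list(alignments = aln, removed = character(0)))
  ov <- overlapsAny(aln, annotations$ncrna, minoverlap = 1L, ignore.strand = TRUE)
  bad_ids <- unique(aln$read_id[ov])
  list(alignments = aln[!aln$read_id %in% bad_ids], removed = bad_ids)
}

#' Sequencing-depth denominator: distinct genome-mapping non-ncRNA reads
#'
#' Counts distinct reads with at least one surviving alignment after ncRNA
#' filtering. This — not the alignment count — is the per-library depth used
#' to normalize cluster length histograms.
#'
#' @param alignments Alignment `GRanges` (ncRNA-filtered) or `mapping_result`.
#' @return Integer read count.
#' @export
mapped_depth <- function(alignments) {
  aln <- as_alignments(alignments)
  length(unique(aln$read_id))
}

#' Write / read alignments as a headered TSV
#'
#' Columns: read_id, chrom, start0 (0-based), end (exclusive), strand,
#' n_hits — i.e. BED-style half-open coordinates on disk, converted from and
#' to the in-memory 1-based `GRanges`.
#'
#' @param alignments Alignment `GRanges` or `mapping_result`.
#' @param path TSV path.
#' @return Invisibly `path` (write) / alignment `GRanges` (read).
#' @export
write_alignments <- function(alignments, path) {
  aln <- as_alignments(alignments)
  df <- data.frame(read_id = aln$read_id,
                   chrom = as.character(seqnames(aln)),
                   start0 = start(aln) - 1L, end = end(aln),
                   strand = as.character(strand(aln)), n_hits = aln$n_hits)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  GRanges(df$chrom, IRanges(df$start0 + 1L, df$end), strand = df$strand,
          read_id = df$read_id, n_hits = df$n_hits)
}
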