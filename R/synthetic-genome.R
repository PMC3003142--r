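#' Specification of a synthetic toy genome
#'
#' Describes a small random genome carrying one designated piRNA cluster,
#' stranded transposon element fragments, and ncRNA intervals. The default
#' demo spec (see [demo_genome_spec()]) emulates a chromosome-4-like telomeric
#' cluster: a 71 kb span whose HeT-A/TART-like fragments all lie on the minus
#' genomic strand, so that the elements' sense strand is the minus strand.
#'
#' @param chromosome_lengths Named integer vector: chromosome name -> length (nt).
#' @param cluster Length-1 `GRanges` or `"chrom:start-end"` string (1-based
#'   inclusive): the cluster span.
#' @param elements `GRanges` of transposon element fragments with `name`
#'   metadata and strand.
#' @param ncrna `GRanges` of ncRNA/pre-miRNA intervals.
#' @param seed Integer random seed for sequence generation.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(chromosome_lengths, cluster, elements = GRanges(),
                        ncrna = GRanges(), seed = 1L) {
  stopifnot(is.numeric(chromosome_lengths), length(chromosome_lengths) >= 1,
            !is.null(names(chromosome_lengths)), all(chromosome_lengths >= 1))
  ann <- annotation_set(cluster, elements = elements, ncrna = ncrna)
  check_bounds <- function(gr, what) {
    if (!length(gr)) return(invisible())
    chr <- as.character(seqnames(gr))
    unknown <- setdiff(chr, names(chromosome_lengths))
    if (length(unknown)) stop(what, " on unknown chromosome(s): ",
                              paste(unknown, collapse = ", "))
    lens <- chromosome_lengths[chr]
    if (any(start(gr) < 1) || any(end(gr) > lens))
      stop(what, " interval out of chromosome bounds")
    if (any(width(gr) < 1)) stop(what, " interval is degenerate")
  }
  check_bounds(ann$cluster, "cluster")
  check_bounds(ann$elements, "element")
  check_bounds(ann$ncrna, "ncRNA")
  structure(list(chromosome_lengths = chromosome_lengths, annotations = ann,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Demo chromosome-4-like genome specification
#'
#' A 100 kb "chr4" carrying a 71 kb cluster (positions 10001-81000, mirroring
#' the 71 kb width of the real telomeric cluster span) with six minus-strand
#' HeT-A/TART-like fragments, two off-cluster ncRNA intervals, plus a 50 kb
#' "chrX" background chromosome that optionally carries one off-cluster
#' telomeric fragment for cluster-attribution experiments.
#'
#' @param seed Integer random seed.
#' @param offcluster_element Logical: include an off-cluster HeT-A-like
#'   fragment on chrX (receives reads only if its fragment weight is set).
#' @return A [genome_spec].
#' @export
demo_genome_spec <- function(seed = 1L, offcluster_element = FALSE) {
  frag_start <- c(12001, 20001, 30001, 40001, 52001, 62001)
  frag_end <- c(18000, 27000, 36000, 48000, 58000, 70000)
  nm <- c("HeT-A_1", "TART_1", "HeT-A_2", "HeT-A_3", "TART_2", "HeT-A_4")
  chroms <- rep("chr4", length(nm))
  if (offcluster_element) {
    frag_start <- c(frag_start, 20001)
    frag_end <- c(frag_end, 26000)
    nm <- c(nm, "HeT-A_X")
    chroms <- c(chroms, "chrX")
  }
  elements <- GRanges(chroms, IRanges(frag_start, frag_end), strand = "-", name = nm)
  ncrna <- GRanges(c("chr4", "chr4", "chrX"),
                   IRanges(c(85001, 90001, 5001), c(85300, 90200, 5160)),
                   name = c("ncRNA_1", "ncRNA_2", "pre-miR_1"))
  genome_spec(c(chr4 = 100000L, chrX = 50000L), "chr4:10001-81000",
              elements = elements, ncrna = ncrna, seed = seed)
}

#' Generate a toy genome and its annotations
#'
#' Draws independent uniform A/C/G/T sequences of the requested lengths.
#' Element fragments are intervals of this random sequence; a minus-strand
#' fragment's sense sequence is the reverse complement of the genomic span.
#' Deterministic for a fixed spec seed: the same spec yields byte-identical
#' sequences.
#'
#' @param spec A [genome_spec].
#' @return List with `genome` ([Biostrings::DNAStringSet], one entry per
#'   chromosome, with `seqlengths` recorded on the annotations) and
#'   `annotations` ([annotation_set]).
#' @export
#' @examples
#' gs <- demo_genome_spec(seed = 7)
#' g <- generate_genome(gs)
#' Biostrings::width(g$genome)
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  seqs <- with_seed(spec$seed, {
    vapply(spec$chromosome_lengths, random_dna, character(1))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(spec$chromosome_lengths)
  list(genome = genome, annotations = spec$annotations)
}

#' Write a genome as FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)
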