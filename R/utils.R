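#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom methods is
NULL

# Default 3'-linker: a fixed arbitrary 20-mer. Only its first 6 bases matter
# for trimming; it is configuration, not a claim about any real protocol.
DEFAULT_LINKER <- "CTGTAGGCACCATCAATCGT"

DNA_BASES <- c("A", "C", "G", "T")

#' Run code with a temporarily fixed RNG state
#'
#' Seeds the generator, runs `code`, and restores the caller's RNG state, so
#' the package's simulators are reproducible without clobbering the session.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Reverse complement of character sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Parse a region string into a GRanges
#'
#' Region strings like `"chr4:1280000-1350999"` are interpreted as 1-based
#' inclusive coordinates, the convention used in genome-browser notation.
#'
#' @param x Region string `"chrom:start-end"`, or a `GRanges` (returned as is).
#' @return A length-1 [GenomicRanges::GRanges].
#' @export
#' @examples
#' parse_region("chr4:1280000-1350999")
parse_region <- function(x) {
  if (is(x, "GRanges")) {
    stopifnot(length(x) == 1)
    return(x)
  }
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", x)
  s <- as.numeric(m[3]); e <- as.numeric(m[4])
  if (s > e) stop("region start exceeds end: ", x)
  GRanges(m[2], IRanges(s, e))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
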