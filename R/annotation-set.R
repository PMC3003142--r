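#' Typed genomic annotation tracks with a designated cluster
#'
#' Bundles the interval tracks the pipeline needs: the designated piRNA
#' cluster span (exactly one interval), the telomeric transposon element
#' fragments (stranded; in the chromosome-4-like cluster their sense strand is
#' the minus genomic strand), and the ncRNA/pre-miRNA intervals whose reads
#' are removed before profiling.
#'
#' @param cluster Length-1 [GenomicRanges::GRanges] or a `"chrom:start-end"`
#'   string (1-based inclusive), the cluster span.
#' @param elements `GRanges` of transposon element fragments, with a `name`
#'   metadata column and strand set.
#' @param ncrna `GRanges` of ncRNA/pre-miRNA intervals (strand ignored).
#' @return An `annotation_set` object (list of sorted `GRanges` tracks).
#' @export
#' @examples
#' ann <- annotation_set("chr4:10001-81000",
#'   elements = GenomicRanges::GRanges("chr4", IRanges::IRanges(12001, 18000),
#'     strand = "-", name = "HeT-A_1"))
annotation_set <- function(cluster, elements = GRanges(), ncrna = GRanges()) {
  cluster <- parse_region(cluster)
  if (length(cluster) != 1) stop("exactly one cluster interval must be designated")
  elements <- as(elements, "GRanges")
  ncrna <- as(ncrna, "GRanges")
  if (length(elements) && is.null(mcols(elements)$name)) {
    mcols(elements)$name <- paste0("element_", seq_along(elements))
  }
  out <- list(
    cluster = cluster,
    elements = sort(elements, ignore.strand = TRUE),
    ncrna = sort(ncrna, ignore.strand = TRUE)
  )
  class(out) <- "annotation_set"
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set\n")
  cat(sprintf("  cluster : %s:%d-%d (%d nt)\n",
              as.character(seqnames(x$cluster)), start(x$cluster),
              end(x$cluster), width(x$cluster)))
  cat(sprintf("  elements: %d fragment(s), %d nt total\n",
              length(x$elements), sum(width(x$elements))))
  cat(sprintf("  ncrna   : %d interval(s)\n", length(x$ncrna)))
  invisible(x)
}

#' Write annotation tracks as BED6 files
#'
#' Files are standard BED: 0-based half-open, six columns
#' (chrom, start, end, name, score, strand).
#'
#' @param annotations An [annotation_set].
#' @param dir Output directory; `cluster.bed`, `elements.bed` and `ncrna.bed`
#'   are written inside it.
#' @return Invisibly, the paths written.
#' @export
write_annotation_set <- function(annotations, dir) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (track in c("cluster", "elements", "ncrna")) {
    gr <- annotations[[track]]
    path <- file.path(dir, paste0(track, ".bed"))
    score(gr) <- 0
    if (is.null(mcols(gr)$name)) mcols(gr)$name <- paste0(track, "_", seq_along(gr))
    names(gr) <- mcols(gr)$name
    rtracklayer::export(gr, path, format = "BED")
    paths[track] <- path
  }
  invisible(paths)
}

#' Read annotation tracks from BED files
#'
#' @param cluster_bed,elements_bed,ncrna_bed Paths to BED files; the element
#'   and ncRNA tracks may be missing/`NULL` (empty track).
#' @return An [annotation_set].
#' @export
read_annotation_set <- function(cluster_bed, elements_bed = NULL, ncrna_bed = NULL) {
  read_track <- function(path) {
    if (is.null(path)) return(GRanges())
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(names(gr)) && is.null(mcols(gr)$name)) mcols(gr)$name <- names(gr)
    gr
  }
  cl <- read_track(cluster_bed)
  annotation_set(cl[1], elements = read_track(elements_bed), ncrna = read_track(ncrna_bed))
}
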