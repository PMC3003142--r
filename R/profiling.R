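#' Cluster-restricted, strand-split, depth-normalized length histogram
#'
#' A read contributes once to bin (strand, length) if at least one of its
#' placements overlaps the cluster span; the strand is taken from that
#' placement. A multi-mapped read whose placements hit the cluster on both
#' strands is assigned to its leftmost cluster placement and a warning
#' counter increments. Abundances are normalized to reads per million
#' depth-countable reads, where depth is the library-wide count of distinct
#' genome-mapping non-ncRNA reads ([mapped_depth()]).
#'
#' @param alignments ncRNA-filtered alignment `GRanges` (or `mapping_result`).
#' @param annotations An [annotation_set]; its `cluster` defines the span.
#' @param depth Normalization denominator from [mapped_depth()] on the same
#'   library (must be > 0).
#' @param min_len,max_len Length bin range (defaults bracket the 19-29 nt
#'   classes).
#' @param genotype Optional label carried on the result.
#' @return A `length_histogram`: `raw` and `normalized` 2 x L matrices
#'   (rows "+", "-"), `depth`, `n_cluster_reads`, `n_strand_ambiguous`.
#' @export
cluster_histogram <- function(alignments, annotations, depth,
                              min_len = 18L, max_len = 30L, genotype = NULL) {
  aln <- as_alignments(alignments)
  stopifnot(inherits(annotations, "annotation_set"))
  if (depth <= 0) stop("depth must be positive to normalize")
  lens <- min_len:max_len
  raw <- matrix(0L, 2, length(lens), dimnames = list(c("+", "-"), lens))
  n_amb <- 0L
  if (length(aln)) {
    sub <- aln[overlapsAny(aln, annotations$cluster, ignore.strand = TRUE)]
    if (length(sub)) {
      strands <- unique(data.frame(id = sub$read_id,
                                   s = as.character(strand(sub))))
      n_amb <- sum(duplicated(strands$id))
      ord <- order(sub$read_id, start(sub))
      chosen <- sub[ord][!duplicated(sub$read_id[ord])]
      len <- width(chosen)
      ok <- len >= min_len & len <= max_len
      tab <- table(factor(as.character(strand(chosen))[ok], levels = c("+", "-")),
                   factor(len[ok], levels = lens))
      raw <- matrix(as.integer(tab), 2, length(lens),
                    dimnames = list(c("+", "-"), lens))
    }
  }
  structure(list(raw = raw, normalized = raw * 1e6 / depth, depth = depth,
                 min_len = min_len, max_len = max_len,
                 n_cluster_reads = sum(raw), n_strand_ambiguous = n_amb,
                 genotype = genotype),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("length_histogram%s: %d cluster reads, depth %d, lengths %d-%d\n",
              if (is.null(x$genotype)) "" else paste0(" [", x$genotype, "]"),
              x$n_cluster_reads, x$depth, x$min_len, x$max_len))
  print(round(x$normalized, 2))
  invisible(x)
}

#' Plot a strand-split length histogram
#'
#' Plus-strand bars up (blue), minus-strand bars down (red), normalized
#' abundance on the y-axis — the conventional rendering of strand-specific
#' small-RNA size profiles.
#'
#' @param x A `length_histogram`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly `x`.
#' @export
plot.length_histogram <- function(x, ...) {
  up <- x$normalized["+", ]
  dn <- -x$normalized["-", ]
  ylim <- range(0, up, dn) * 1.05
  graphics::barplot(up, col = "steelblue3", border = NA, ylim = ylim,
                    xlab = "length (nt)",
                    ylab = "reads per million (plus up, minus down)",
                    main = x$genotype %||% "", ...)
  graphics::barplot(dn, col = "firebrick3", border = NA, add = TRUE, axes = FALSE)
  graphics::abline(h = 0)
  invisible(x)
}

#' Size-class abundances: 19-22 nt (excluding 21 nt) vs 23-29 nt
#'
#' Sums normalized abundance over the short class — exactly lengths 19, 20
#' and 22, excluding the entire 21 nt endo-siRNA bin — and the long piRNA
#' class, 23-29 nt inclusive, separately per strand.
#'
#' @param hist A `length_histogram` whose bins cover 19-29 nt.
#' @param genotype Optional label (defaults to the histogram's).
#' @return A `size_class_summary` data.frame with columns `genotype`,
#'   `size_class` ("short_19_22_excl21" / "long_23_29"), `strand`,
#'   `abundance` (reads per million).
#' @export
size_class_summary <- function(hist, genotype = NULL) {
  stopifnot(inherits(hist, "length_histogram"))
  if (hist$min_len > 19 || hist$max_len < 29)
    stop("histogram bins must cover 19-29 nt")
  short <- c("19", "20", "22")
  long <- as.character(23:29)
  out <- data.frame(
    genotype = genotype %||% hist$genotype %||% NA_character_,
    size_class = rep(c("short_19_22_excl21", "long_23_29"), each = 2),
    strand = rep(c("+", "-"), 2),
    abundance = c(sum(hist$normalized["+", short]), sum(hist$normalized["-", short]),
                  sum(hist$normalized["+", long]), sum(hist$normalized["-", long])),
    stringsAsFactors = FALSE)
  class(out) <- c("size_class_summary", "data.frame")
  out
}

#' Mutant/wild-type fold-change table for size classes
#'
#' Elementwise mutant/wt ratios of normalized abundance per (size class,
#' strand). A zero wild-type abundance makes the ratio undefined: the row is
#' flagged, never silently dropped.
#'
#' @param mutant,wt `size_class_summary` objects with identical class sets.
#' @return Data.frame with `genotype`, `size_class`, `strand`, `mutant`,
#'   `wt`, `ratio`, `undefined`.
#' @export
fold_change <- function(mutant, wt) {
  stopifnot(inherits(mutant, "size_class_summary"),
            inherits(wt, "size_class_summary"))
  key <- function(x) paste(x$size_class, x$strand)
  if (!setequal(key(mutant), key(wt)) || nrow(mutant) != nrow(wt))
    stop("mismatched size-class sets")
  m <- mutant[order(key(mutant)), ]
  w <- wt[order(key(wt)), ]
  undef <- w$abundance == 0
  data.frame(genotype = m$genotype, size_class = m$size_class, strand = m$strand,
             mutant = m$abundance, wt = w$abundance,
             ratio = ifelse(undef, NA_real_, m$abundance / w$abundance),
             undefined = undef, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of telomeric-element reads attributable to the cluster
#'
#' Denominator: reads with at least one placement overlapping any telomeric
#' element fragment (the `elements` track, genome-wide). Numerator: those
#' reads that also have at least one placement inside the cluster span.
#'
#' @param alignments Alignment `GRanges` or `mapping_result` (ncRNA-filtered).
#' @param annotations An [annotation_set].
#' @return List with `fraction` (NA and `undefined = TRUE` when no telomeric
#'   reads exist), `n_telomeric`, `n_in_cluster`.
#' @export
cluster_attribution <- function(alignments, annotations) {
  aln <- as_alignments(alignments)
  stopifnot(inherits(annotations, "annotation_set"))
  telo_ids <- unique(aln$read_id[overlapsAny(aln, annotations$elements,
                                             ignore.strand = TRUE)])
  cl_ids <- unique(aln$read_id[overlapsAny(aln, annotations$cluster,
                                           ignore.strand = TRUE)])
  num <- length(intersect(telo_ids, cl_ids))
  den <- length(telo_ids)
  list(fraction = if (den == 0) NA_real_ else num / den,
       n_telomeric = den, n_in_cluster = num, undefined = den == 0)
}

#' Ping-pong 5'-overlap signature
#'
#' For every plus/minus alignment pair on the same chromosome, the 5'-to-5'
#' overlap is the inclusive distance from the plus read's 5' end (its genomic
#' start) to the minus read's 5' end (its genomic end):
#' `minus_end - plus_start + 1`. Pair counts are histogrammed over overlaps
#' 1-30; ping-pong amplification produces a characteristic excess at exactly
#' 10 nt, summarized by a z-score of the 10 nt bin against the remaining bins.
#'
#' @param alignments Alignment `GRanges` or `mapping_result`.
#' @param region Optional region (`GRanges` or string) to restrict to.
#' @param max_overlap Largest overlap tabulated.
#' @return A `pingpong_signature`: `counts` (named vector over 1..max),
#'   `z10`, `modal` (overlap with the highest pair count), `n_pairs`.
#' @export
ping_pong_signature <- function(alignments, region = NULL, max_overlap = 30L) {
  aln <- as_alignments(alignments)
  if (!is.null(region))
    aln <- aln[overlapsAny(aln, parse_region(region), ignore.strand = TRUE)]
  counts <- stats::setNames(numeric(max_overlap), seq_len(max_overlap))
  for (chrom in unique(as.character(seqnames(aln)))) {
    sub <- aln[seqnames(aln) == chrom]
    sp <- start(sub[strand(sub) == "+"])
    em <- end(sub[strand(sub) == "-"])
    if (!length(sp) || !length(em)) next
    tp <- table(sp); tm <- table(em)
    kp <- as.integer(names(tp)); km <- as.integer(names(tm))
    for (d in seq_len(max_overlap)) {
      idx <- match(kp + d - 1L, km)
      ok <- !is.na(idx)
      if (any(ok)) counts[d] <- counts[d] + sum(as.numeric(tp[ok]) * as.numeric(tm[idx[ok]]))
    }
  }
  others <- counts[-10]
  z10 <- if (length(counts) >= 10 && stats::sd(others) > 0)
    (counts[["10"]] - mean(others)) / stats::sd(others) else NA_real_
  structure(list(counts = counts, z10 = z10,
                 modal = as.integer(names(which.max(counts))),
                 n_pairs = sum(counts)),
            class = "pingpong_signature")
}

#' @export
print.pingpong_signature <- function(x, ...) {
  cat(sprintf("pingpong_signature: %g pairs, modal overlap %d nt, z(10 nt) = %.2f\n",
              x$n_pairs, x$modal, x$z10))
  invisible(x)
}
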