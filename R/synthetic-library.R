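LIBRARY_CLASSES <- c("pirna_minus_23_29", "pirna_plus_23_29", "endo_sirna_21",
                     "short_minus_19_22", "background_offcluster", "unmatched_junk")

#' Default per-class insert length distributions
#'
#' piRNA classes peak at 25-26 nt within 23-29 nt; the endo-siRNA class is a
#' sharp 21 nt peak; the short minus-strand class is supported on 19, 20 and
#' 22 nt only (21 nt is reserved for the endo-siRNA class); background inserts
#' are uniform over 18-29 nt.
#'
#' @return Named list of probability vectors (names are lengths in nt).
#' @export
default_length_dists <- function() {
  list(
    pirna_minus_23_29 = c("23" = 0.08, "24" = 0.15, "25" = 0.25, "26" = 0.22,
                          "27" = 0.15, "28" = 0.10, "29" = 0.05),
    pirna_plus_23_29 = c("23" = 0.08, "24" = 0.15, "25" = 0.25, "26" = 0.22,
                         "27" = 0.15, "28" = 0.10, "29" = 0.05),
    endo_sirna_21 = c("21" = 1),
    short_minus_19_22 = c("19" = 0.3, "20" = 0.4, "22" = 0.3),
    background_offcluster = stats::setNames(rep(1 / 12, 12), 18:29)
  )
}

#' Specification of a synthetic small-RNA library
#'
#' Describes one genotype's library as a mixture of read classes: minus- and
#' plus-strand 23-29 nt piRNAs from the cluster's element fragments, the sharp
#' 21 nt minus-strand endo-siRNA peak, the shorter 19-22 nt minus-strand
#' species (supported on 19/20/22 nt), off-cluster background, and junk reads
#' that carry no linker and are discarded at trimming.
#'
#' @param genotype Free-text genotype label.
#' @param n_reads Number of reads to generate.
#' @param class_weights Named sampling probabilities over the read classes
#'   (see `LIBRARY_CLASSES`); must sum to 1 within 1e-9. Missing classes get
#'   weight 0.
#' @param linker 3'-linker sequence (>= 6 nt) appended to every genuine insert.
#' @param read_length Fixed raw read length; inserts plus linker are truncated
#'   to it. Must be at least `max(insert length) + 6` so the linker 6-mer
#'   survives truncation.
#' @param length_dists Per-class insert length distributions, as from
#'   [default_length_dists()].
#' @param fragment_weights Optional numeric weights over the annotation's
#'   element fragments used when sampling on-cluster read origins; default is
#'   proportional to fragment width.
#' @param pingpong Optional `list(n_pairs, overlap = 10, length = 25)`: append
#'   forced ping-pong read pairs whose 5' ends overlap by `overlap` nt.
#' @param error_rate Per-base substitution rate applied to the final read;
#'   defaults to 0 because mapping is full-match only.
#' @param seed Integer random seed.
#' @return A `library_spec` object.
#' @export
library_spec <- function(genotype, n_reads, class_weights,
                         linker = DEFAULT_LINKER, read_length = 40L,
                         length_dists = default_length_dists(),
                         fragment_weights = NULL, pingpong = NULL,
                         error_rate = 0, seed = 1L) {
  stopifnot(is.character(genotype), length(genotype) == 1,
            n_reads >= 0, nchar(linker) >= 6, error_rate >= 0, error_rate <= 1)
  unknown <- setdiff(names(class_weights), LIBRARY_CLASSES)
  if (length(unknown)) stop("unknown read class(es): ", paste(unknown, collapse = ", "))
  w <- stats::setNames(numeric(length(LIBRARY_CLASSES)), LIBRARY_CLASSES)
  w[names(class_weights)] <- class_weights
  if (any(w < 0)) stop("class weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("class weights must sum to 1 (within 1e-9)")
  check_support <- function(cls, allowed) {
    d <- length_dists[[cls]]
    if (is.null(d)) {
      if (w[cls] > 0) stop("no length distribution for class ", cls)
      return(invisible())
    }
    lens <- as.integer(names(d))
    if (!all(lens %in% allowed))
      stop(cls, " length support must lie in {", paste(allowed, collapse = ","), "}")
    if (abs(sum(d) - 1) > 1e-9) stop(cls, " length distribution must sum to 1")
  }
  check_support("short_minus_19_22", c(19L, 20L, 22L))
  check_support("endo_sirna_21", 21L)
  check_support("pirna_minus_23_29", 23:29)
  check_support("pirna_plus_23_29", 23:29)
  max_len <- max(unlist(lapply(length_dists, function(d) as.integer(names(d)))))
  if (read_length < max_len + 6)
    stop("read_length must be >= max insert length + 6 to keep the linker detectable")
  if (!is.null(pingpong)) {
    pingpong$overlap <- pingpong$overlap %||% 10L
    pingpong$length <- pingpong$length %||% 25L
    stopifnot(pingpong$n_pairs >= 1, pingpong$overlap >= 1,
              pingpong$length >= pingpong$overlap)
  }
  structure(list(genotype = genotype, n_reads = as.integer(n_reads),
                 class_weights = w, linker = toupper(linker),
                 read_length = as.integer(read_length),
                 length_dists = length_dists,
                 fragment_weights = fragment_weights, pingpong = pingpong,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "library_spec")
}

#' Wild-type-like library specification
#'
#' Default class mixture emulating a wild-type ovary library restricted to the
#' telomeric cluster: abundant minus-strand 23-29 nt piRNAs (the elements'
#' sense strand is the minus genomic strand), fewer plus-strand piRNAs, a
#' 21 nt endo-siRNA peak, a distinct 19-22 nt minus-strand species, plus
#' off-cluster background and 5% linker-less junk.
#'
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param ... Passed to [library_spec()].
#' @return A `library_spec`.
#' @export
wt_library_spec <- function(n_reads = 2e5, seed = 1L, ...) {
  library_spec("wt", n_reads,
               class_weights = c(pirna_minus_23_29 = 0.38, pirna_plus_23_29 = 0.12,
                                 endo_sirna_21 = 0.08, short_minus_19_22 = 0.12,
                                 background_offcluster = 0.25, unmatched_junk = 0.05),
               seed = seed, ...)
}

#' Derive a mutant library specification by depleting classes
#'
#' Divides the named class weights by the given factors and rebalances the
#' freed probability mass into the off-cluster background class, leaving the
#' junk weight unchanged. Because background reads still map, the fraction of
#' depth-countable reads is preserved, so the planted depth-normalized fold
#' change of a depleted class equals exactly `1/factor` in expectation.
#'
#' @param wt A wild-type `library_spec`.
#' @param depletion Named numeric vector of depletion factors, e.g.
#'   `c(short_minus_19_22 = 5)`. Factors < 1 enrich.
#' @param genotype Label for the mutant.
#' @param seed Integer seed.
#' @return A `library_spec` with a `planted_fold` attribute holding the
#'   expected mutant/wt normalized ratio per depleted class.
#' @export
mutant_library_spec <- function(wt, depletion, genotype, seed = wt$seed + 1L) {
  stopifnot(inherits(wt, "library_spec"), !is.null(names(depletion)),
            all(names(depletion) %in% setdiff(LIBRARY_CLASSES,
                                              c("background_offcluster", "unmatched_junk"))),
            all(depletion > 0))
  w <- wt$class_weights
  freed <- sum(w[names(depletion)] * (1 - 1 / depletion))
  w[names(depletion)] <- w[names(depletion)] / depletion
  w["background_offcluster"] <- w["background_offcluster"] + freed
  if (w["background_offcluster"] < 0) stop("enrichment exceeds available background mass")
  spec <- library_spec(genotype, wt$n_reads, class_weights = w, linker = wt$linker,
                       read_length = wt$read_length, length_dists = wt$length_dists,
                       fragment_weights = wt$fragment_weights,
                       error_rate = wt$error_rate, seed = seed)
  attr(spec, "planted_fold") <- 1 / depletion
  spec
}

# Sample insert origins within element fragments for one on-cluster class.
sample_fragment_origins <- function(n, frags, fw, lengths, probs) {
  idx <- sample.int(length(frags), n, replace = TRUE, prob = fw)
  len <- lengths[sample.int(length(lengths), n, replace = TRUE, prob = probs)]
  wd <- width(frags)[idx]
  if (any(len > wd)) stop("requested insert longer than its source fragment")
  start <- start(frags)[idx] + floor(stats::runif(n) * (wd - len + 1))
  data.frame(chrom = as.character(seqnames(frags))[idx],
             start = as.integer(start), end = as.integer(start + len - 1L))
}

extract_inserts <- function(gch, chrom, start, end, minus) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(gch[[ch]], start[i], end[i])
  }
  if (any(minus)) out[minus] <- revcomp(out[minus])
  out
}

#' Generate a raw small-RNA library with ground truth
#'
#' Every genuine read is a genome-derived insert with the 3'-linker appended
#' and the whole truncated to the fixed read length (random bases pad short
#' reads after the linker, as a real sequencer would read past it).
#' `unmatched_junk` reads contain no occurrence of the linker's first 6-mer
#' anywhere, so trimming discards them. A ground-truth table (read id ->
#' class, origin coordinates, strand) is always returned alongside the reads;
#' downstream tests compare against it rather than re-deriving truth.
#'
#' @param genome [Biostrings::DNAStringSet] from [generate_genome()].
#' @param annotations Matching [annotation_set].
#' @param spec A [library_spec].
#' @return List with `reads` (named character vector of raw read sequences),
#'   `truth` (data.frame: read_id, class, chrom, start, end, strand,
#'   insert_length; coordinates 1-based inclusive, NA for junk) and `spec`.
#' @export
#' @examples
#' g <- generate_genome(demo_genome_spec(seed = 2))
#' lib <- generate_library(g$genome, g$annotations,
#'   wt_library_spec(n_reads = 500, seed = 3))
#' table(lib$truth$class)
generate_library <- function(genome, annotations, spec) {
  stopifnot(inherits(spec, "library_spec"), inherits(annotations, "annotation_set"))
  on_cluster <- c("pirna_minus_23_29", "pirna_plus_23_29", "endo_sirna_21",
                  "short_minus_19_22")
  if (any(spec$class_weights[on_cluster] > 0) && length(annotations$elements) == 0)
    stop("on-cluster read classes require element fragments in the annotations")
  gch <- as.list(as.character(genome))
  sixmer <- substr(spec$linker, 1, 6)
  frags <- annotations$elements
  fw <- spec$fragment_weights %||% width(frags)

  with_seed(spec$seed, {
    cls <- sample(LIBRARY_CLASSES, spec$n_reads, replace = TRUE,
                  prob = spec$class_weights)
    truth <- data.frame(read_id = sprintf("%s_r%07d", spec$genotype,
                                          seq_len(spec$n_reads)),
                        class = cls, chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_,
                        insert_length = NA_integer_, stringsAsFactors = FALSE)
    insert <- character(spec$n_reads)

    minus_of <- c(pirna_minus_23_29 = TRUE, pirna_plus_23_29 = FALSE,
                  endo_sirna_21 = TRUE, short_minus_19_22 = TRUE)
    for (cl in on_cluster) {
      i <- which(cls == cl)
      if (!length(i)) next
      d <- spec$length_dists[[cl]]
      org <- sample_fragment_origins(length(i), frags, fw, as.integer(names(d)), d)
      truth$chrom[i] <- org$chrom
      truth$start[i] <- org$start
      truth$end[i] <- org$end
      truth$strand[i] <- if (minus_of[[cl]]) "-" else "+"
      truth$insert_length[i] <- org$end - org$start + 1L
      insert[i] <- extract_inserts(gch, org$chrom, org$start, org$end,
                                   rep(minus_of[[cl]], length(i)))
    }

    i <- which(cls == "background_offcluster")
    if (length(i)) {
      d <- spec$length_dists[["background_offcluster"]]
      chrlen <- vapply(gch, nchar, integer(1))
      n <- length(i)
      chrom <- character(n); st <- integer(n); en <- integer(n)
      todo <- seq_len(n)
      cl_chr <- as.character(seqnames(annotations$cluster))
      cl_start <- start(annotations$cluster); cl_end <- end(annotations$cluster)
      while (length(todo)) {
        m <- length(todo)
        ch <- sample(names(chrlen), m, replace = TRUE, prob = chrlen)
        len <- as.integer(sample(names(d), m, replace = TRUE, prob = d))
        s <- 1L + floor(stats::runif(m) * (chrlen[ch] - len + 1))
        e <- as.integer(s + len - 1L)
        chrom[todo] <- ch; st[todo] <- as.integer(s); en[todo] <- e
        bad <- ch == cl_chr & s <= cl_end & e >= cl_start
        todo <- todo[bad]
      }
      strand <- sample(c("+", "-"), n, replace = TRUE)
      truth$chrom[i] <- chrom; truth$start[i] <- st; truth$end[i] <- en
      truth$strand[i] <- strand
      truth$insert_length[i] <- en - st + 1L
      insert[i] <- extract_inserts(gch, chrom, st, en, strand == "-")
    }

    i <- which(cls == "unmatched_junk")
    if (length(i)) {
      junk <- vapply(seq_along(i), function(k) random_dna(spec$read_length),
                     character(1))
      bad <- grepl(sixmer, junk, fixed = TRUE)
      while (any(bad)) {
        junk[bad] <- vapply(seq_len(sum(bad)),
                            function(k) random_dna(spec$read_length), character(1))
        bad <- grepl(sixmer, junk, fixed = TRUE)
      }
      insert[i] <- junk
    }

    if (!is.null(spec$pingpong)) {
      pp <- make_pingpong_reads(gch, frags, fw, spec)
      truth <- rbind(truth, pp$truth)
      insert <- c(insert, pp$insert)
      cls <- c(cls, pp$truth$class)
    }

    is_junk <- cls == "unmatched_junk"
    reads <- insert
    if (any(!is_junk)) {
      core <- paste0(insert[!is_junk], spec$linker)
      short <- nchar(core) < spec$read_length
      if (any(short)) {
        pad <- vapply(pmax(spec$read_length - nchar(core[short]), 0),
                      random_dna, character(1))
        core[short] <- paste0(core[short], pad)
      }
      reads[!is_junk] <- substr(core, 1, spec$read_length)
    }
    if (spec$error_rate > 0) reads <- mutate_reads(reads, spec$error_rate)
    names(reads) <- truth$read_id
    list(reads = reads, truth = truth, spec = spec)
  })
}

# Forced ping-pong pairs: a plus-strand read whose 5' end (genomic start) and
# a minus-strand read whose 5' end (genomic end) overlap by exactly `overlap`
# nt, both drawn from the same element fragment.
make_pingpong_reads <- function(gch, frags, fw, spec) {
  pp <- spec$pingpong
  n <- pp$n_pairs; L <- pp$length; ov <- pp$overlap
  wd <- width(frags)
  ok <- wd >= 2 * L - ov
  if (!any(ok)) stop("no element fragment can host a ping-pong pair")
  idx <- sample(which(ok), n, replace = TRUE, prob = fw[ok])
  # plus read [s, s+L-1]; minus read 5' at s+ov-1, interval [s+ov-L, s+ov-1]
  lo <- start(frags)[idx] + (L - ov)
  hi <- end(frags)[idx] - L + 1L
  s <- lo + floor(stats::runif(n) * (hi - lo + 1))
  plus <- data.frame(chrom = as.character(seqnames(frags))[idx],
                     start = as.integer(s), end = as.integer(s + L - 1L),
                     strand = "+", class = "pingpong_plus")
  minus <- data.frame(chrom = plus$chrom, start = as.integer(s + ov - L),
                      end = as.integer(s + ov - 1L), strand = "-",
                      class = "pingpong_minus")
  both <- rbind(plus, minus)
  truth <- data.frame(read_id = sprintf("%s_pp%06d", spec$genotype,
                                        seq_len(nrow(both))),
                      class = both$class, chrom = both$chrom, start = both$start,
                      end = both$end, strand = both$strand,
                      insert_length = both$end - both$start + 1L,
                      stringsAsFactors = FALSE)
  insert <- extract_inserts(gch, both$chrom, both$start, both$end,
                            both$strand == "-")
  list(truth = truth, insert = insert)
}

mutate_reads <- function(reads, rate) {
  vapply(reads, function(r) {
    b <- strsplit(r, "")[[1]]
    hit <- stats::runif(length(b)) < rate
    if (any(hit)) b[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write a generated library as FASTQ
#'
#' Plain 4-line records with dummy Phred+33 qualities (`I` = Q40).
#'
#' @param lib Result of [generate_library()], or a named character vector of
#'   read sequences.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_library_fastq <- function(lib, path) {
  reads <- if (is.list(lib)) lib$reads else lib
  stopifnot(!is.null(names(reads)))
  qual <- strrep("I", nchar(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read small-RNA reads from FASTQ or FASTA
#' @param path Input path; format inferred from the first character.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1), 1, 1)
  fmt <- if (first == "@") "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}
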