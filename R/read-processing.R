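#' Trim the 3'-linker from raw reads
#'
#' For each read, the leftmost occurrence of the 6-mer exactly matching the
#' linker's first six bases is located; the insert is everything 5' of it.
#' Matching is literal and case-insensitive; an `N` in the read never matches.
#' Reads without the 6-mer are discarded and counted. An insert whose linker
#' sits at position 1 is empty and is left to the length filter to remove —
#' trimming itself never special-cases it.
#'
#' @param reads Named character vector of raw read sequences (names = read ids).
#' @param linker Linker sequence, at least 6 nt.
#' @return A `trim_result` list: `inserts` (named character vector, possibly
#'   containing empty strings), `discarded` (ids with no 6-mer match),
#'   `n_input`.
#' @export
#' @examples
#' trim_linker(c(r1 = "ACGTACGTCTGTAGTT", r2 = "ACGT"), "CTGTAGGCACCATCAATCGT")
trim_linker <- function(reads, linker = DEFAULT_LINKER) {
  if (nchar(linker) < 6) stop("linker must be at least 6 nt")
  stopifnot(is.character(reads))
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  if (any(nchar(reads) == 0)) stop("reads must be non-empty")
  sixmer <- toupper(substr(linker, 1, 6))
  seqs <- toupper(reads)
  k <- regexpr(sixmer, seqs, fixed = TRUE)
  hit <- k > 0
  inserts <- substr(seqs[hit], 1, k[hit] - 1)
  names(inserts) <- names(reads)[hit]
  structure(list(inserts = inserts, discarded = names(reads)[!hit],
                 n_input = length(reads)),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf("trim_result: %d reads in, %d inserts, %d discarded (no linker 6-mer)\n",
              x$n_input, length(x$inserts), length(x$discarded)))
  invisible(x)
}

#' Filter inserts by length
#'
#' Retains inserts with `min_len <= length <= max_len`; removed inserts are
#' tallied by length. The default 18-30 nt window brackets the 19-29 nt size
#' classes the profiling quantifies.
#'
#' @param inserts Named character vector of insert sequences, or a
#'   `trim_result` (its `inserts` are taken and the accounting carried over).
#' @param min_len,max_len Inclusive length bounds.
#' @return A `length_filter_result` list: `inserts`, `removed_by_length`
#'   (named integer vector: length -> count removed), plus the carried
#'   `discarded`/`n_input` when a `trim_result` was supplied.
#' @export
length_filter <- function(inserts, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  carried <- NULL
  if (inherits(inserts, "trim_result")) {
    carried <- inserts
    inserts <- inserts$inserts
  }
  len <- nchar(inserts)
  keep <- len >= min_len & len <= max_len
  removed <- table(len[!keep])
  structure(list(inserts = inserts[keep],
                 removed_by_length = stats::setNames(as.integer(removed),
                                                     names(removed)),
                 discarded = carried$discarded %||% character(0),
                 n_input = carried$n_input %||% length(inserts)),
            class = "length_filter_result")
}

#' Read-conservation accounting across trimming and length filtering
#'
#' Asserts the exact identity reads_in = inserts_out + discarded_no_linker +
#' discarded_length.
#'
#' @param x A `length_filter_result` that carried trim accounting.
#' @return Named integer vector of the accounting terms (invisibly errors if
#'   conservation fails).
#' @export
trim_conservation <- function(x) {
  stopifnot(inherits(x, "length_filter_result"))
  out <- c(reads_in = x$n_input, inserts_out = length(x$inserts),
           discarded_no_linker = length(x$discarded),
           discarded_length = sum(x$removed_by_length))
  if (out["reads_in"] != sum(out[-1]))
    stop("read conservation violated: ", paste(out, collapse = " / "))
  out
}

#' Write inserts as FASTA with a discard report
#'
#' @param x A `length_filter_result` (or named character vector of inserts).
#' @param fasta_path Output FASTA path for the retained inserts.
#' @param report_path Optional TSV path for the discard report
#'   (category, detail, count).
#' @return Invisibly, `fasta_path`.
#' @export
write_inserts <- function(x, fasta_path, report_path = NULL) {
  inserts <- if (is.list(x)) x$inserts else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(inserts), fasta_path)
  if (!is.null(report_path) && is.list(x)) {
    rep <- rbind(
      data.frame(category = "no_linker", detail = "", count = length(x$discarded)),
      if (length(x$removed_by_length))
        data.frame(category = "length", detail = names(x$removed_by_length),
                   count = as.integer(x$removed_by_length))
    )
    utils::write.table(rep, report_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(fasta_path)
}
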