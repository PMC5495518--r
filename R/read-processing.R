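# FASTQ handling, barcode demultiplexing and 3'-adapter trimming for small-RNA
# libraries. Reads travel as tibbles (read_id, sequence, quality).

#' Read a FASTQ (or FASTA) file into a tibble
#'
#' @param path Path to a FASTQ/FASTA file (gzip transparent).
#' @param format `"fastq"` or `"fasta"`.
#' @return A tibble with columns `read_id`, `sequence`, `quality` (`NA` for
#'   FASTA input).
#' @export
read_fastq <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    return(tibble(
      read_id = names(x), sequence = unname(as.character(x)),
      quality = NA_character_
    ))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads to FASTQ
#'
#' Reads without quality strings get a constant `"I"` (Phred 40) quality.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`.
#' @param path Output path (`.gz` allowed).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else rep(NA_character_, nrow(reads))
  miss <- is.na(qual)
  qual[miss] <- vapply(nchar(reads$sequence[miss]),
                       function(n) strrep("I", n), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(qual)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Assign reads to libraries by exact barcode prefix
#'
#' Each read is assigned to the library whose barcode exactly matches the
#' read's 5' prefix; the barcode is stripped from sequence and quality.
#' Non-matching reads are kept under library `"unassigned"` with their
#' sequence intact.
#'
#' @param reads Tibble with `read_id`, `sequence`, optionally `quality`.
#' @param barcodes Named character vector label -> barcode; barcodes must be
#'   distinct and of equal length.
#' @return The input tibble with a `library` column prepended and barcode
#'   prefixes removed from assigned reads.
#' @export
demultiplex <- function(reads, barcodes) {
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    abort("`barcodes` must be a named character vector")
  }
  if (anyDuplicated(barcodes)) abort("duplicate barcode sequences")
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) abort("barcodes must all have the same length")
  prefix <- substr(reads$sequence, 1L, bl)
  lab <- names(barcodes)[match(prefix, barcodes)]
  hit <- !is.na(lab)
  out <- reads
  out$library <- if_else(hit, lab, "unassigned")
  out$sequence[hit] <- substring(out$sequence[hit], bl + 1L)
  if ("quality" %in% names(out)) {
    has_q <- hit & !is.na(out$quality)
    out$quality[has_q] <- substring(out$quality[has_q], bl + 1L)
  }
  dplyr::relocate(out, "library")
}

#' Trim a 3' sequencing adapter from reads
#'
#' Removes a full internal adapter match and everything 3' of it; otherwise
#' removes the longest read suffix that exactly matches a prefix of the
#' adapter, provided the match is at least `min_overlap` bases. Reads shorter
#' than `min_len` after trimming are rejected (dropped, counted in the
#' `trim_stats` attribute); trimming never lengthens a read.
#'
#' @param reads Tibble with `read_id`, `sequence`, optionally `quality`.
#' @param adapter Adapter sequence (5' end must be adjacent to the insert).
#' @param min_overlap Minimum adapter bases required to trim (default 3).
#' @param min_len Minimum insert length kept after trimming (default 18).
#' @return Tibble of kept reads with trimmed `sequence`/`quality`; attribute
#'   `trim_stats` holds `n_input`, `n_trimmed`, `n_rejected`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L, min_len = 18L) {
  min_overlap <- assert_count(min_overlap, "min_overlap", 1L)
  min_len <- assert_count(min_len, "min_len", 1L)
  if (nchar(adapter) < min_overlap) abort("`adapter` must be at least `min_overlap` long")
  seqs <- reads$sequence
  L <- nchar(seqs)
  keep_len <- L

  # full internal adapter: cut at the leftmost occurrence
  at <- regexpr(adapter, seqs, fixed = TRUE)
  full <- at > 0L
  keep_len[full] <- at[full] - 1L

  # suffix-prefix overlaps, longest first
  todo <- !full
  k_hi <- if (length(L)) min(nchar(adapter) - 1L, max(L)) else 0L
  ks <- if (k_hi >= min_overlap) seq(k_hi, min_overlap) else integer()
  for (k in ks) {
    if (!any(todo)) break
    idx <- which(todo & L >= k)
    if (!length(idx)) next
    m <- substr(seqs[idx], L[idx] - k + 1L, L[idx]) == substr(adapter, 1L, k)
    keep_len[idx[m]] <- L[idx[m]] - k
    todo[idx[m]] <- FALSE
  }

  out <- reads
  out$sequence <- substr(seqs, 1L, keep_len)
  if ("quality" %in% names(out)) {
    has_q <- !is.na(out$quality)
    out$quality[has_q] <- substr(out$quality[has_q], 1L, keep_len[has_q])
  }
  kept <- keep_len >= min_len
  res <- out[kept, , drop = FALSE]
  attr(res, "trim_stats") <- tibble(
    n_input = length(seqs),
    n_trimmed = sum(keep_len < L),
    n_rejected = sum(!kept)
  )
  res
}
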