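# Ungapped, mismatch-free mapping of trimmed small-RNA reads to a locus-scale
# reference, plus SAM/BED6 ingestion of externally mapped reads. The matching
# engine is Biostrings::matchPDict over the unique read sequences; placements
# are identical to an exhaustive string scan (property-tested).

#' Construct a mapped small-RNA library
#'
#' @param alignments Tibble with columns `read_id`, `start` (0-based),
#'   `length`, `strand` (`+`/`-`, relative to the reference).
#' @param total_reads Library-size denominator for reads-per-million scaling;
#'   must be >= the number of aligned reads.
#' @param name Library name.
#' @param reference_name,reference_length Reference the coordinates refer to.
#' @return An object of class `sirna_library`.
#' @export
sirna_library <- function(alignments, total_reads, name = "library",
                          reference_name = "locus", reference_length = NA_integer_) {
  alignments <- as_tibble(alignments)[, c("read_id", "start", "length", "strand")]
  total_reads <- assert_count(total_reads, "total_reads", 0L)
  if (total_reads < length(unique(alignments$read_id))) {
    abort("`total_reads` must be >= the number of aligned reads")
  }
  if (nrow(alignments) && !all(alignments$strand %in% c("+", "-"))) {
    abort("alignment strand must be '+' or '-'")
  }
  structure(
    list(
      name = name, total_reads = total_reads, alignments = alignments,
      reference_name = reference_name,
      reference_length = as.integer(reference_length)
    ),
    class = "sirna_library"
  )
}

#' @export
print.sirna_library <- function(x, ...) {
  cat(sprintf(
    "<sirna_library> %s: %d aligned / %d total reads on %s\n",
    x$name, nrow(x$alignments), x$total_reads, x$reference_name
  ))
  invisible(x)
}

#' Map reads to a locus reference by exact ungapped matching
#'
#' Each read is searched mismatch-free on both strands of the reference. Reads
#' with 1..`max_hits` placements contribute all their placements; reads with
#' more are discarded as multi-mappers; reads containing `N` are unmapped.
#' A minus-strand placement at `start` means the reverse complement of the
#' read equals `reference[start, start+length)`.
#'
#' @param reads Tibble with a `sequence` column (and optionally `read_id`), or
#'   a character vector of sequences.
#' @param reference Reference sequence (character or
#'   [Biostrings::DNAString]).
#' @param max_hits Maximum number of placements for a read to be kept
#'   (default 1, unique mappers only).
#' @param name Library name.
#' @param reference_name Name recorded for the reference.
#' @return A [sirna_library()]; `total_reads` is the number of input reads.
#'   Attribute `map_stats` counts `n_input`, `n_mapped`, `n_unmapped`,
#'   `n_multi`, `n_with_n`.
#' @export
map_reads <- function(reads, reference, max_hits = 1L, name = "library",
                      reference_name = "locus") {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read_%d", seq_along(reads)), sequence = reads)
  }
  if (!"read_id" %in% names(reads)) {
    reads <- mutate(reads, read_id = sprintf("read_%d", row_number()))
  }
  max_hits <- assert_count(max_hits, "max_hits", 1L)
  reference <- toupper(as.character(reference))
  if (!nzchar(reference)) abort("empty reference sequence")
  ref_dna <- Biostrings::DNAString(reference)
  n_input <- nrow(reads)

  seqs <- toupper(reads$sequence)
  has_n <- grepl("[^ACGT]", seqs)
  uniq <- unique(seqs[!has_n])

  hits <- list()
  if (length(uniq)) {
    by_len <- split(uniq, nchar(uniq))
    for (grp in by_len) {
      w <- nchar(grp[1L])
      if (w > nchar(reference)) next
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(grp))
      # plus strand: read equals reference substring
      st <- Biostrings::startIndex(Biostrings::matchPDict(pd, ref_dna))
      nh <- lengths(st)
      plus <- tibble(
        sequence = rep(grp, nh), start = unlist(st, use.names = FALSE) - 1L,
        length = w, strand = "+"
      )
      # minus strand: reverse complement of read equals reference substring
      pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(Biostrings::DNAStringSet(grp)))
      st_rc <- Biostrings::startIndex(Biostrings::matchPDict(pd_rc, ref_dna))
      nh_rc <- lengths(st_rc)
      minus <- tibble(
        sequence = rep(grp, nh_rc), start = unlist(st_rc, use.names = FALSE) - 1L,
        length = w, strand = "-"
      )
      hits[[length(hits) + 1L]] <- bind_rows(plus, minus)
    }
  }
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) {
    hits <- tibble(sequence = character(), start = integer(),
                   length = integer(), strand = character())
  }
  n_hits <- table(hits$sequence)
  keep_seqs <- names(n_hits)[n_hits <= max_hits]
  placed <- filter(hits, .data$sequence %in% keep_seqs)
  reads$sequence <- seqs
  aligned <- inner_join(
    select(reads, "read_id", "sequence"), placed,
    by = "sequence", relationship = "many-to-many"
  )
  mapped_seq <- unique(placed$sequence)
  n_with_n <- sum(has_n)
  n_multi <- sum(seqs %in% names(n_hits)[n_hits > max_hits])
  n_mapped <- sum(seqs %in% mapped_seq)
  lib <- sirna_library(
    select(aligned, "read_id", "start", "length", "strand"),
    total_reads = n_input, name = name,
    reference_name = reference_name, reference_length = nchar(reference)
  )
  attr(lib, "map_stats") <- tibble(
    n_input = n_input, n_mapped = n_mapped,
    n_unmapped = n_input - n_mapped, n_multi = n_multi, n_with_n = n_with_n
  )
  lib
}

#' Ingest externally mapped reads from SAM or BED6
#'
#' SAM `POS` (1-based) is converted to 0-based starts; flag bit 16 gives the
#' minus strand; unmapped records are skipped but still counted into
#' `total_reads`. BED6 is taken as 0-based half-open with the strand column.
#'
#' @param path Path to a `.sam` or `.bed` file.
#' @param reference_name Reference/chromosome to extract.
#' @param total_reads Library-size denominator; default (`NULL`) uses the
#'   number of records in the file (including unmapped SAM records).
#' @param format `"auto"`, `"sam"` or `"bed6"`.
#' @param name Library name.
#' @return A [sirna_library()].
#' @export
read_alignments <- function(path, reference_name, total_reads = NULL,
                            format = c("auto", "sam", "bed6"), name = "library") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed6"
  }
  if (format == "sam") {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
      error = function(e) abort(sprintf("failed to parse SAM '%s': %s", path, conditionMessage(e)))
    )
    on.exit(unlink(bam), add = TRUE)
    res <- Rsamtools::scanBam(
      bam,
      param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "qwidth", "strand"))
    )[[1L]]
    rec <- tibble(
      read_id = res$qname,
      rname = as.character(res$rname),
      mapped = bitwAnd(res$flag, 4L) == 0L,
      start = res$pos - 1L,
      length = res$qwidth,
      strand = if_else(bitwAnd(res$flag, 16L) == 16L, "-", "+")
    )
    n_records <- nrow(rec)
    aligned <- filter(rec, .data$mapped, .data$rname == reference_name)
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bed"),
      error = function(e) abort(sprintf("failed to parse BED '%s': %s", path, conditionMessage(e)))
    )
    n_records <- length(gr)
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == reference_name]
    aligned <- tibble(
      read_id = gr$name %||% sprintf("read_%d", seq_along(gr)),
      start = GenomicRanges::start(gr) - 1L,
      length = GenomicRanges::width(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
    if (any(aligned$strand == "*")) abort("BED6 input must carry a strand column")
  }
  total <- total_reads %||% n_records
  sirna_library(
    select(aligned, "read_id", "start", "length", "strand"),
    total_reads = total, name = name, reference_name = reference_name
  )
}

#' Write a library's alignments to BED6
#'
#' @param lib A [sirna_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(lib, path) {
  stopifnot(inherits(lib, "sirna_library"))
  a <- lib$alignments
  gr <- GenomicRanges::GRanges(
    lib$reference_name,
    IRanges::IRanges(start = a$start + 1L, width = a$length),
    strand = a$strand, name = a$read_id, score = 0L
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
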