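#' Single-transcript gene model in 0-based half-open coordinates
#'
#' Represents the structure of one transcript: its chromosome, strand, and an
#' ordered set of exons on the genomic axis. Introns are the gaps between
#' consecutive exons. All coordinates are 0-based, half-open (`[start, end)`);
#' conversion from 1-based formats happens only in the readers
#' ([read_gene_model()]).
#'
#' Exons are stored sorted by genomic start regardless of strand; transcription
#' orientation is resolved through `strand` wherever "upstream" (5' of the
#' transcript) matters, so minus-strand genes behave symmetrically.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with columns `start`, `end` (0-based half-open),
#'   non-overlapping, each of length >= 1.
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exons` (tibble), `tss` and `transcript_end` (the genomic span;
#'   for a minus-strand gene the biological start is at `transcript_end - 1`).
#' @examples
#' g <- gene_model("g1", "chr2", "+",
#'                 data.frame(start = c(100, 300), end = c(200, 400)))
#' introns(g)
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'")
  exons <- as_tibble(exons)[, c("start", "end")]
  exons <- arrange(exons, .data$start)
  if (nrow(exons) < 1L) abort("a gene model needs at least one exon")
  if (any(exons$end - exons$start < 1L)) abort("every exon must have length >= 1")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    abort("exons must be non-overlapping")
  }
  if (nrow(exons) > 1L && any(exons$start[-1L] - exons$end[-nrow(exons)] < 1L)) {
    abort("introns (gaps between exons) must have length >= 1")
  }
  structure(
    list(
      gene_id = as.character(gene_id), chrom = as.character(chrom),
      strand = strand,
      exons = exons,
      tss = min(exons$start), transcript_end = max(exons$end)
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s %s:%d-%d (%s), %d exon(s), %d intron(s)\n",
    x$gene_id, x$chrom, x$tss, x$transcript_end, x$strand,
    nrow(x$exons), max(nrow(x$exons) - 1L, 0L)
  ))
  invisible(x)
}

gene_span_length <- function(g) g$transcript_end - g$tss

#' Introns of a gene model
#'
#' @param g A [gene_model()].
#' @return A tibble with columns `start`, `end` (0-based half-open), one row
#'   per intron in genomic order; zero rows for an intron-less gene.
#' @export
introns <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  n <- nrow(g$exons)
  if (n < 2L) return(tibble(start = integer(), end = integer()))
  tibble(start = g$exons$end[-n], end = g$exons$start[-1L])
}

# exons ordered 5'->3' in transcription orientation
exons_tx_order <- function(g) {
  if (g$strand == "+") g$exons else g$exons[rev(seq_len(nrow(g$exons))), ]
}

#' Enumerate exons, introns and splice junctions with their sizes
#'
#' Produces the feature set used for size-normalized per-feature coverage:
#' every exon and intron (genomic axis), every exon|intron (5' splice site) and
#' intron|exon (3' splice site) boundary on the genomic axis, and every
#' exon-exon junction on the spliced (cDNA) axis. Features are numbered 5'->3'
#' in transcription orientation.
#'
#' A junction's "size" is the number of distinct start positions from which a
#' read of length `read_length` can span it with at least `min_overhang` bases
#' on each side, i.e. `read_length - 2 * min_overhang + 1`. This makes the
#' size-normalized junction coverage directly comparable to per-base exon and
#' intron densities under uniform read placement.
#'
#' @param g A [gene_model()].
#' @param read_length Read length assumed for junction sizing (default 21,
#'   the canonical siRNA length).
#' @param min_overhang Minimum bases required on each side of a boundary for a
#'   read to span it (default 1).
#' @return A tibble with columns `feature` (label), `kind` (`exon`, `intron`,
#'   `exon_intron_5p`, `intron_exon_3p`, `exon_exon`), `axis` (`genomic` or
#'   `spliced`), `start`, `end` (intervals; `NA` for junctions), `pos`
#'   (junction boundary, 0-based index of the first base after the boundary;
#'   `NA` for intervals), `size` (bases or spanning start positions), and
#'   `flank_5p`/`flank_3p` (labels of the flanking features for junctions).
#' @export
derive_features <- function(g, read_length = 21L, min_overhang = 1L) {
  stopifnot(inherits(g, "gene_model"))
  read_length <- assert_count(read_length, "read_length", 2L)
  min_overhang <- assert_count(min_overhang, "min_overhang", 1L)
  if (read_length < 2L * min_overhang) {
    abort("`read_length` must be >= 2 * `min_overhang`")
  }
  jsize <- read_length - 2L * min_overhang + 1L

  ex <- exons_tx_order(g)
  n_ex <- nrow(ex)
  ins <- introns(g)
  if (g$strand == "-" && nrow(ins) > 0L) ins <- ins[rev(seq_len(nrow(ins))), ]

  rows <- list()
  rows$exons <- tibble(
    feature = sprintf("exon_%d", seq_len(n_ex)), kind = "exon",
    axis = "genomic", start = ex$start, end = ex$end,
    pos = NA_integer_, size = ex$end - ex$start,
    flank_5p = NA_character_, flank_3p = NA_character_
  )
  if (nrow(ins) > 0L) {
    ni <- nrow(ins)
    rows$introns <- tibble(
      feature = sprintf("intron_%d", seq_len(ni)), kind = "intron",
      axis = "genomic", start = ins$start, end = ins$end,
      pos = NA_integer_, size = ins$end - ins$start,
      flank_5p = NA_character_, flank_3p = NA_character_
    )
    # genomic boundary positions in transcription order:
    # exon_i -> intron_i (5' splice site), intron_i -> exon_{i+1} (3' site)
    j5_pos <- if (g$strand == "+") ins$start else ins$end
    j3_pos <- if (g$strand == "+") ins$end else ins$start
    rows$j5 <- tibble(
      feature = sprintf("junction_5p_%d", seq_len(ni)), kind = "exon_intron_5p",
      axis = "genomic", start = NA_integer_, end = NA_integer_,
      pos = as.integer(j5_pos), size = jsize,
      flank_5p = sprintf("exon_%d", seq_len(ni)),
      flank_3p = sprintf("intron_%d", seq_len(ni))
    )
    rows$j3 <- tibble(
      feature = sprintf("junction_3p_%d", seq_len(ni)), kind = "intron_exon_3p",
      axis = "genomic", start = NA_integer_, end = NA_integer_,
      pos = as.integer(j3_pos), size = jsize,
      flank_5p = sprintf("intron_%d", seq_len(ni)),
      flank_3p = sprintf("exon_%d", seq_len(ni) + 1L)
    )
    # exon-exon junctions live on the spliced axis; position = cumulative
    # spliced length of the first i exons (transcription order)
    sp_pos <- cumsum(ex$end - ex$start)[seq_len(ni)]
    rows$jee <- tibble(
      feature = sprintf("junction_ee_%d", seq_len(ni)), kind = "exon_exon",
      axis = "spliced", start = NA_integer_, end = NA_integer_,
      pos = as.integer(sp_pos), size = jsize,
      flank_5p = sprintf("exon_%d", seq_len(ni)),
      flank_3p = sprintf("exon_%d", seq_len(ni) + 1L)
    )
  }
  out <- bind_rows(rows)
  attr(out, "read_length") <- read_length
  attr(out, "min_overhang") <- min_overhang
  out
}

#' Spliced (cDNA) sequence of a gene model
#'
#' Concatenates the exon sequences in transcription order; for a minus-strand
#' gene the result is reverse-complemented so it reads 5'->3' of the mRNA.
#'
#' @param g A [gene_model()].
#' @param reference Reference sequence of the chromosome/locus the model's
#'   coordinates refer to (character or [Biostrings::DNAString]), position 1
#'   of the string = genomic position 0.
#' @return A single character string, the spliced transcript sequence.
#' @export
spliced_sequence <- function(g, reference) {
  reference <- as.character(reference)
  if (g$transcript_end > nchar(reference)) {
    abort("gene model extends beyond the reference sequence")
  }
  parts <- substring(reference, g$exons$start + 1L, g$exons$end)
  cdna <- paste(parts, collapse = "")
  if (g$strand == "-") cdna <- revcomp(cdna) else cdna
}

#' Describe a cas9 cut site and its protospacer
#'
#' The cut position is a 0-based boundary between two bases. The protospacer
#' interval (default length 20) locates reads derived from the sgRNA itself;
#' coverage analyses exclude this interval (plus a pad) so the sgRNA-derived
#' read peak does not distort density ratios.
#'
#' @param cut_position 0-based boundary position of the blunt cut.
#' @param protospacer_start,protospacer_end Half-open interval of the sgRNA
#'   target sequence; defaults place a 20-nt protospacer so the cut falls
#'   between positions 17 and 18 of the protospacer (3 nt from the PAM-proximal
#'   end), the canonical cas9 geometry.
#' @param label Free-text label.
#' @param chrom Optional chromosome name.
#' @return An object of class `cut_site`.
#' @export
cut_site <- function(cut_position,
                     protospacer_start = cut_position - 17L,
                     protospacer_end = cut_position + 3L,
                     label = "cut", chrom = NA_character_) {
  cut_position <- assert_count(cut_position, "cut_position")
  protospacer_start <- assert_count(protospacer_start, "protospacer_start")
  protospacer_end <- assert_count(protospacer_end, "protospacer_end", 1L)
  if (protospacer_end <= protospacer_start) {
    abort("protospacer interval must be non-empty")
  }
  if (cut_position < protospacer_start - 1L || cut_position > protospacer_end + 1L) {
    abort("cut_position must lie inside or adjacent to the protospacer")
  }
  structure(
    list(
      cut_position = cut_position,
      protospacer_start = protospacer_start, protospacer_end = protospacer_end,
      label = as.character(label), chrom = as.character(chrom)
    ),
    class = "cut_site"
  )
}

#' @export
print.cut_site <- function(x, ...) {
  cat(sprintf(
    "<cut_site> %s cut at %d, protospacer [%d,%d)\n",
    x$label, x$cut_position, x$protospacer_start, x$protospacer_end
  ))
  invisible(x)
}
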