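# Gene-model and cut-site I/O. External formats keep their native coordinate
# conventions (GFF3 1-based closed, BED 0-based half-open); everything internal
# is 0-based half-open.

#' Read a single-transcript gene model from GFF3 or BED12
#'
#' GFF3 files may structure the transcript as `gene -> mRNA -> exon` or
#' `gene -> exon`; the reader follows `Parent` links from the record whose
#' `ID` (or `Name`) equals `gene_id` down to the exon level. BED12 files are
#' matched on the `name` field; blocks become exons.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param gene_id Identifier of the gene to extract.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, gene_id, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "bed12") read_gene_model_bed12(path, gene_id)
  else read_gene_model_gff3(path, gene_id)
}

read_gene_model_gff3 <- function(path, gene_id) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(sprintf("failed to parse GFF3 '%s': %s", path, conditionMessage(e)))
  )
  mc <- S4Vectors::mcols(gr)
  ids <- as.character(mc$ID %||% rep(NA_character_, length(gr)))
  nms <- as.character(mc$Name %||% rep(NA_character_, length(gr)))
  parents <- mc$Parent
  parent_chr <- if (is.null(parents)) rep(NA_character_, length(gr)) else {
    vapply(as.list(parents), function(p) if (length(p)) p[[1L]] else NA_character_, character(1))
  }
  hit <- which(ids == gene_id | nms == gene_id)
  if (length(hit) == 0L) {
    abort(sprintf("gene '%s' not found in '%s'", gene_id, path), class = "dsbsirna_not_found")
  }
  # walk Parent links until exon-level records are reached
  want <- ids[hit]
  exon_idx <- integer()
  for (i in 1:3) {
    child <- which(parent_chr %in% want)
    if (length(child) == 0L) break
    is_exon <- tolower(as.character(mc$type[child])) == "exon"
    exon_idx <- child[is_exon]
    if (length(exon_idx) > 0L) break
    want <- ids[child]
  }
  if (length(exon_idx) == 0L) {
    # gene annotated as a single exon-less record: treat its span as one exon
    exon_idx <- hit[1L]
  }
  sub <- gr[exon_idx]
  gene_model(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(sub))[1L],
    strand = as.character(GenomicRanges::strand(sub))[1L],
    # GFF3 is 1-based closed: start-1 converts to 0-based half-open
    exons = tibble(
      start = GenomicRanges::start(sub) - 1L,
      end = GenomicRanges::end(sub)
    )
  )
}

read_gene_model_bed12 <- function(path, gene_id) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) abort(sprintf("failed to parse BED '%s': %s", path, conditionMessage(e)))
  )
  hit <- which(gr$name == gene_id)
  if (length(hit) == 0L) {
    abort(sprintf("gene '%s' not found in '%s'", gene_id, path), class = "dsbsirna_not_found")
  }
  x <- gr[hit[1L]]
  blk <- rtracklayer::blocks(x)[[1L]]
  gene_model(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(x)),
    strand = as.character(GenomicRanges::strand(x)),
    exons = tibble(start = GenomicRanges::start(blk) - 1L, end = GenomicRanges::end(blk))
  )
}

#' Write a gene model to GFF3 or BED12
#'
#' Inverse of [read_gene_model()]; `read(write(g)) == g` on valid models.
#'
#' @param g A [gene_model()].
#' @param path Output path.
#' @param format `"gff3"` or `"bed12"`.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(g, path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "gene_model"))
  if (format == "bed12") {
    exon_gr <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$exons$start + 1L, g$exons$end), strand = g$strand
    )
    grl <- GenomicRanges::GRangesList(setNames(list(exon_gr), g$gene_id))
    rtracklayer::export(rtracklayer::asBED(grl), path, format = "bed")
  } else {
    n_ex <- nrow(g$exons)
    gr <- GenomicRanges::GRanges(
      g$chrom,
      IRanges::IRanges(
        c(g$tss + 1L, g$exons$start + 1L), c(g$transcript_end, g$exons$end)
      ),
      strand = g$strand,
      type = c("gene", rep("exon", n_ex)),
      ID = c(g$gene_id, sprintf("%s:exon:%d", g$gene_id, seq_len(n_ex)))
    )
    S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
      c(list(character(0)), as.list(rep(g$gene_id, n_ex)))
    )
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Read cut sites from a TSV or YAML file
#'
#' TSV input needs columns `chrom`, `cut_position`, `protospacer_start`,
#' `protospacer_end` and optionally `label`; YAML input is a list of mappings
#' with the same keys. Coordinates are 0-based (positions are boundaries,
#' intervals half-open).
#'
#' @param path Path to a `.tsv`/`.txt` or `.yaml`/`.yml` file.
#' @return A tibble with one row per cut site.
#' @export
read_cut_sites <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    df <- purrr::map_dfr(recs, as_tibble)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
  }
  need <- c("chrom", "cut_position", "protospacer_start", "protospacer_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("cut-site file lacks column(s): %s", paste(miss, collapse = ", ")))
  if (!"label" %in% names(df)) df$label <- sprintf("cut_%d", seq_len(nrow(df)))
  as_tibble(df[, c(need, "label")])
}

#' Turn rows of a cut-site table into `cut_site` objects
#'
#' @param df A tibble as returned by [read_cut_sites()].
#' @return A named list of [cut_site()] objects (names = labels).
#' @export
cut_sites_from_table <- function(df) {
  out <- purrr::pmap(df, function(chrom, cut_position, protospacer_start,
                                   protospacer_end, label, ...) {
    cut_site(cut_position, protospacer_start, protospacer_end, label, chrom)
  })
  setNames(out, df$label)
}

#' Write cut sites to TSV
#'
#' @param sites A tibble (as from [read_cut_sites()]) or list of [cut_site()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cut_sites <- function(sites, path) {
  if (!is.data.frame(sites)) {
    sites <- purrr::map_dfr(sites, function(s) {
      tibble(
        chrom = s$chrom, cut_position = s$cut_position,
        protospacer_start = s$protospacer_start,
        protospacer_end = s$protospacer_end, label = s$label
      )
    })
  }
  readr::write_tsv(sites, path)
  invisible(path)
}
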