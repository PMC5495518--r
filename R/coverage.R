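# Strand-resolved reads-per-million coverage over a transcript window, read
# end-position traces, and the upstream/downstream per-base density ratio
# around a cut site with the sgRNA-derived peak excluded.

#' Strand-resolved RPM coverage and end-position traces over a transcript
#'
#' Per-base coverage is the number of reads overlapping each base of
#' `[tss, transcript_end)`, scaled to reads per million by the library's
#' `total_reads`. Reads are split into gene-relative sense (read strand equals
#' gene strand) and antisense. End traces place each sense read at its 5' end
#' and each antisense read at its 3' end — for a plus-strand gene both are the
#' read's leftmost genomic coordinate (an antisense read extends from its 3'
#' end downstream); for a minus-strand gene both are the rightmost. Only reads
#' lying wholly inside the window enter the end traces.
#'
#' @param lib A [sirna_library()].
#' @param g A [gene_model()].
#' @param read_length_filter Length-2 numeric, inclusive read-length bounds
#'   (default `c(18, 24)`, the Dicer product range).
#' @return A tibble of class `coverage_trace` with columns `pos` (0-based
#'   genomic), `rpm_sense`, `rpm_antisense`, `end_sense`, `end_antisense`;
#'   attributes `library_size`, `gene` and `n_reads_used`.
#' @export
build_coverage <- function(lib, g, read_length_filter = c(18L, 24L)) {
  stopifnot(inherits(lib, "sirna_library"), inherits(g, "gene_model"))
  if (lib$total_reads <= 0L) abort("library size (total_reads) must be positive")
  lo <- g$tss
  hi <- g$transcript_end
  n <- hi - lo
  a <- filter(
    lib$alignments,
    .data$length >= read_length_filter[1L], .data$length <= read_length_filter[2L],
    .data$start < hi, .data$start + .data$length > lo
  )
  scale <- 1e6 / lib$total_reads

  cov_of <- function(starts, lens) {
    # difference-array coverage over [lo, hi), read intervals clipped
    d <- numeric(n + 1L)
    s <- pmax(starts, lo) - lo
    e <- pmin(starts + lens, hi) - lo
    ok <- e > s
    if (any(ok)) {
      ds <- tabulate(s[ok] + 1L, nbins = n + 1L)
      de <- tabulate(e[ok] + 1L, nbins = n + 1L)
      d <- ds - de
    }
    cumsum(d)[seq_len(n)]
  }
  end_of <- function(starts, lens) {
    inside <- starts >= lo & starts + lens <= hi
    pos <- if (g$strand == "+") starts[inside] else starts[inside] + lens[inside] - 1L
    tabulate(pos - lo + 1L, nbins = n)
  }

  sense <- a$strand == g$strand
  out <- tibble(
    pos = seq.int(lo, hi - 1L),
    rpm_sense = cov_of(a$start[sense], a$length[sense]) * scale,
    rpm_antisense = cov_of(a$start[!sense], a$length[!sense]) * scale,
    end_sense = end_of(a$start[sense], a$length[sense]) * scale,
    end_antisense = end_of(a$start[!sense], a$length[!sense]) * scale
  )
  attr(out, "library_size") <- lib$total_reads
  attr(out, "gene") <- g
  attr(out, "n_reads_used") <- nrow(a)
  class(out) <- c("coverage_trace", class(out))
  out
}

#' Upstream/downstream per-base density ratio around a cut site
#'
#' The transcript is split at the cut into an upstream region (between the
#' transcription start site and the cut, in transcription orientation) and a
#' downstream region (cut to transcript 3' end). Bases inside the protospacer
#' interval extended by `exclusion_pad` are removed from both numerator and
#' per-base divisor, so reads derived from the sgRNA itself do not contribute.
#' The ratio of mean per-base RPM (upstream / downstream) is the measure of
#' break-induced siRNA production; it is reported for both strands combined
#' and per strand. A zero downstream mean yields `ratio = NA` with
#' `ratio_defined = FALSE`, never an infinity.
#'
#' @param trace A [build_coverage()] result.
#' @param g A [gene_model()].
#' @param cut A [cut_site()] whose position lies inside the transcript.
#' @param exclusion_pad Extra bases excluded on each side of the protospacer
#'   (default 5).
#' @return A tibble of class `region_density`, one row per strand mode
#'   (`both`, `sense`, `antisense`), with columns `strand_mode`,
#'   `upstream_mean_rpm`, `downstream_mean_rpm`, `ratio`, `ratio_defined`,
#'   `upstream_bases`, `downstream_bases`, `excluded_start`, `excluded_end`.
#' @export
cut_ratio <- function(trace, g, cut, exclusion_pad = 5L) {
  stopifnot(inherits(trace, "coverage_trace"), inherits(g, "gene_model"),
            inherits(cut, "cut_site"))
  exclusion_pad <- assert_count(exclusion_pad, "exclusion_pad")
  cp <- cut$cut_position
  if (cp <= g$tss || cp >= g$transcript_end) {
    abort("cut_position must lie strictly inside [tss, transcript_end)")
  }
  ex_lo <- cut$protospacer_start - exclusion_pad
  ex_hi <- cut$protospacer_end + exclusion_pad

  pos <- trace$pos
  excluded <- pos >= ex_lo & pos < ex_hi
  before_cut <- pos < cp       # genomic left of the cut
  up <- if (g$strand == "+") before_cut else !before_cut
  up_keep <- up & !excluded
  dn_keep <- !up & !excluded
  if (!any(up_keep) || !any(dn_keep)) {
    abort("upstream or downstream region is empty after sgRNA exclusion")
  }

  one <- function(vals, mode) {
    um <- mean(vals[up_keep])
    dm <- mean(vals[dn_keep])
    defined <- dm > 0
    tibble(
      strand_mode = mode,
      upstream_mean_rpm = um, downstream_mean_rpm = dm,
      ratio = if (defined) um / dm else NA_real_,
      ratio_defined = defined,
      upstream_bases = sum(up_keep), downstream_bases = sum(dn_keep),
      excluded_start = ex_lo, excluded_end = ex_hi
    )
  }
  out <- bind_rows(
    one(trace$rpm_sense + trace$rpm_antisense, "both"),
    one(trace$rpm_sense, "sense"),
    one(trace$rpm_antisense, "antisense")
  )
  class(out) <- c("region_density", class(out))
  out
}

#' Write a coverage trace as bedGraph tracks
#'
#' Emits four bedGraph files (`<prefix>.sense.cov.bedGraph`,
#' `.antisense.cov.bedGraph`, `.sense.ends.bedGraph`,
#' `.antisense.ends.bedGraph`), 0-based half-open, values in RPM. Zero-valued
#' runs are omitted, as is conventional for sparse tracks.
#'
#' @param trace A [build_coverage()] result.
#' @param out_prefix Path prefix for the four files.
#' @return Character vector of the four paths, invisibly.
#' @export
write_tracks <- function(trace, out_prefix) {
  stopifnot(inherits(trace, "coverage_trace"))
  g <- attr(trace, "gene")
  paths <- c(
    sense.cov = paste0(out_prefix, ".sense.cov.bedGraph"),
    antisense.cov = paste0(out_prefix, ".antisense.cov.bedGraph"),
    sense.ends = paste0(out_prefix, ".sense.ends.bedGraph"),
    antisense.ends = paste0(out_prefix, ".antisense.ends.bedGraph")
  )
  cols <- c("rpm_sense", "rpm_antisense", "end_sense", "end_antisense")
  for (i in seq_along(cols)) {
    v <- trace[[cols[i]]]
    r <- rle(v)
    ends0 <- cumsum(r$lengths)
    starts0 <- ends0 - r$lengths
    keep <- r$values != 0
    gr <- GenomicRanges::GRanges(
      rep(g$chrom, sum(keep)),
      IRanges::IRanges(start = trace$pos[1L] + starts0[keep] + 1L,
                       end = trace$pos[1L] + ends0[keep]),
      score = r$values[keep]
    )
    rtracklayer::export(gr, paths[i], format = "bedGraph")
  }
  invisible(paths)
}

#' Read bedGraph tracks written by [write_tracks()] back into a trace
#'
#' @param out_prefix Prefix used in [write_tracks()].
#' @param g The [gene_model()] defining the window.
#' @param library_size Library size to record on the trace.
#' @return A `coverage_trace` tibble.
#' @export
read_tracks <- function(out_prefix, g, library_size = NA_integer_) {
  n <- gene_span_length(g)
  read_one <- function(suffix) {
    path <- paste0(out_prefix, ".", suffix, ".bedGraph")
    gr <- rtracklayer::import(path, format = "bedGraph")
    v <- numeric(n)
    if (length(gr)) {
      s <- GenomicRanges::start(gr) - 1L - g$tss
      e <- GenomicRanges::end(gr) - g$tss
      for (i in seq_along(gr)) v[(s[i] + 1L):e[i]] <- gr$score[i]
    }
    v
  }
  out <- tibble(
    pos = seq.int(g$tss, g$transcript_end - 1L),
    rpm_sense = read_one("sense.cov"),
    rpm_antisense = read_one("antisense.cov"),
    end_sense = read_one("sense.ends"),
    end_antisense = read_one("antisense.ends")
  )
  attr(out, "library_size") <- library_size
  attr(out, "gene") <- g
  class(out) <- c("coverage_trace", class(out))
  out
}
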