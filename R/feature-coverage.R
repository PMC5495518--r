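# Size-normalized per-feature siRNA coverage (exons, introns, splice
# junctions), junction-spanning read counting on the genomic and spliced axes,
# replicate comparisons and the 2x2 enrichment test.

#' Count reads per feature and normalize to feature size
#'
#' An exon or intron counts every read whose interval intersects it. A genomic
#' splice-boundary junction counts reads that span the boundary with at least
#' `min_overhang` bases on each side. Counts are scaled to RPM with the
#' library's `total_reads` and divided by the feature size (bases for
#' intervals, number of spanning start positions for junctions), so uniform
#' read placement gives equal normalized coverage across feature kinds.
#'
#' @param lib A [sirna_library()].
#' @param features A [derive_features()] tibble (genomic-axis features are
#'   counted; spliced-axis rows are passed through with `NA` counts — see
#'   [count_spliced_junction_reads()]).
#' @param g The [gene_model()] the features came from.
#' @param min_overhang Junction overhang rule; should match the value used in
#'   [derive_features()] (default 1).
#' @param replicate_id Label stored alongside the counts.
#' @return A tibble with `feature`, `kind`, `axis`, `size`, `read_count`,
#'   `rpm`, `normalized_coverage` and `replicate_id`.
#' @export
count_feature_reads <- function(lib, features, g, min_overhang = 1L,
                                replicate_id = lib$name) {
  stopifnot(inherits(lib, "sirna_library"))
  min_overhang <- assert_count(min_overhang, "min_overhang", 1L)
  a <- lib$alignments
  scale <- 1e6 / lib$total_reads
  count_one <- function(kind, axis, start, end, pos) {
    if (axis != "genomic") return(NA_integer_)
    if (kind %in% c("exon", "intron")) {
      sum(a$start < end & a$start + a$length > start)
    } else {
      sum(a$start <= pos - min_overhang & a$start + a$length >= pos + min_overhang)
    }
  }
  out <- mutate(
    features,
    read_count = purrr::pmap_int(
      list(.data$kind, .data$axis, .data$start, .data$end, .data$pos), count_one
    ),
    rpm = .data$read_count * scale,
    normalized_coverage = .data$rpm / .data$size,
    replicate_id = replicate_id
  )
  select(out, "feature", "kind", "axis", "size", "read_count", "rpm",
         "normalized_coverage", "replicate_id")
}

#' Count exon-exon junction-spanning reads on the spliced axis
#'
#' Reads are mapped to the spliced (cDNA) sequence of the gene; a read spanning
#' an exon-exon boundary with at least `min_overhang` bases on each side counts
#' for that junction. By default, reads that also map to the unspliced genomic
#' sequence are excluded, so only reads that can *only* derive from a spliced
#' product are counted (disable with `exclude_genomic = FALSE`).
#'
#' @param reads Tibble with `sequence` (and optionally `read_id`), or a
#'   character vector — trimmed reads, not yet mapped.
#' @param g A [gene_model()] with at least one intron.
#' @param reference Genomic reference sequence for the locus.
#' @param min_overhang Minimum overhang on each side of the boundary.
#' @param exclude_genomic Drop reads that also map to the genomic axis.
#' @param max_hits Passed to the mapper on both axes.
#' @return A tibble with one row per exon-exon junction: `feature`,
#'   `spliced_pos`, `read_count`; attribute `n_spliced_mapped` and
#'   `n_excluded_genomic` record the mapping bookkeeping.
#' @export
count_spliced_junction_reads <- function(reads, g, reference, min_overhang = 1L,
                                         exclude_genomic = TRUE, max_hits = 1L) {
  stopifnot(inherits(g, "gene_model"))
  min_overhang <- assert_count(min_overhang, "min_overhang", 1L)
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read_%d", seq_along(reads)), sequence = reads)
  }
  feats <- derive_features(g, read_length = max(2L * min_overhang, 21L),
                           min_overhang = min_overhang)
  ee <- filter(feats, .data$kind == "exon_exon")
  if (nrow(ee) == 0L) {
    return(tibble(feature = character(), spliced_pos = integer(),
                  read_count = integer()))
  }
  cdna <- spliced_sequence(g, reference)
  lib_sp <- map_reads(reads, cdna, max_hits = max_hits, reference_name = "spliced")
  al <- lib_sp$alignments
  n_excluded <- 0L
  if (exclude_genomic && nrow(al)) {
    lib_gen <- map_reads(reads, reference, max_hits = max_hits,
                         reference_name = "genomic")
    genomic_ids <- unique(lib_gen$alignments$read_id)
    n_excluded <- length(unique(al$read_id[al$read_id %in% genomic_ids]))
    al <- filter(al, !.data$read_id %in% genomic_ids)
  }
  counts <- vapply(ee$pos, function(p) {
    sum(al$start <= p - min_overhang & al$start + al$length >= p + min_overhang)
  }, integer(1))
  out <- tibble(feature = ee$feature, spliced_pos = ee$pos, read_count = counts)
  attr(out, "n_spliced_mapped") <- length(unique(lib_sp$alignments$read_id))
  attr(out, "n_excluded_genomic") <- n_excluded
  out
}

#' Compare normalized coverage of two features (or feature groups) across replicates
#'
#' Per replicate, the normalized coverage of group `a` and group `b` is
#' computed (group members averaged), then a paired two-sided Student's t-test
#' is run on the per-replicate values. Replicates share library-level scaling,
#' which is why the paired form is used. Zero variance of the paired
#' differences is reported as `degenerate = TRUE` with `p_value = NA`.
#'
#' @param fc A long tibble of per-replicate feature coverages — rows from
#'   [count_feature_reads()] over several libraries (must contain `feature`,
#'   `normalized_coverage`, `replicate_id`).
#' @param feature_a,feature_b Feature label(s); vectors are treated as groups
#'   and averaged within each replicate.
#' @return A one-row tibble: `feature_a`, `feature_b`, `n_replicates`,
#'   `mean_a`, `mean_b`, `mean_difference`, `t_statistic`, `p_value`,
#'   `degenerate`.
#' @export
compare_features <- function(fc, feature_a, feature_b) {
  per_rep <- function(labels) {
    x <- filter(fc, .data$feature %in% labels)
    if (!all(labels %in% x$feature)) {
      abort(sprintf("feature(s) not present: %s",
                    paste(setdiff(labels, x$feature), collapse = ", ")))
    }
    summarise(group_by(x, .data$replicate_id),
              value = mean(.data$normalized_coverage), .groups = "drop")
  }
  av <- per_rep(feature_a)
  bv <- per_rep(feature_b)
  j <- inner_join(av, bv, by = "replicate_id", suffix = c("_a", "_b"))
  n <- nrow(j)
  if (n < 2L) abort("need >= 2 replicates with both features present")
  d <- j$value_a - j$value_b
  degenerate <- isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- t.test(j$value_a, j$value_b, paired = TRUE, alternative = "two.sided")
  }
  tibble(
    feature_a = paste(feature_a, collapse = "+"),
    feature_b = paste(feature_b, collapse = "+"),
    n_replicates = n,
    mean_a = mean(j$value_a), mean_b = mean(j$value_b),
    mean_difference = mean(d),
    t_statistic = unname(tt$statistic), p_value = unname(tt$p.value),
    degenerate = degenerate
  )
}

#' Pearson chi-square enrichment test on a 2x2 table
#'
#' Tests whether the hit rate differs between two groups (e.g. Prp19-complex
#' members versus the remaining spliceosome components in an RNAi screen).
#'
#' @param hits_1,n_1 Hits and group size for group 1.
#' @param hits_2,n_2 Hits and group size for group 2.
#' @param correction `"none"` (plain Pearson chi-square, 1 df) or `"yates"`
#'   (continuity correction).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `correction`,
#'   `rate_1`, `rate_2`.
#' @export
enrichment_test <- function(hits_1, n_1, hits_2, n_2,
                            correction = c("none", "yates")) {
  correction <- match.arg(correction)
  tab <- matrix(c(hits_1, n_1 - hits_1, hits_2, n_2 - hits_2),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) abort("counts must be non-negative and hits <= n")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correction == "yates"))
  tibble(
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = unname(ct$p.value), correction = correction,
    rate_1 = hits_1 / n_1, rate_2 = hits_2 / n_2
  )
}
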