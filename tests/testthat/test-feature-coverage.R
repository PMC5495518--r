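test_that("junction spanning follows the overhang rule", {
  g <- gene_model("g", "c", "+", data.frame(start = c(0, 200), end = c(100, 300)))
  feats <- derive_features(g, 21, 1)
  mk <- function(starts) {
    sirna_library(
      tibble::tibble(read_id = sprintf("r%d", seq_along(starts)),
                     start = as.integer(starts), length = 21L, strand = "+"),
      total_reads = 1e6
    )
  }
  # read [95,116) spans the boundary at 100 with 5 and 16 flanking bases
  fc <- count_feature_reads(mk(95), feats, g, min_overhang = 1)
  expect_equal(fc$read_count[fc$feature == "junction_5p_1"], 1)
  # read [100,121) has 0 bases left of the boundary: not spanning
  fc2 <- count_feature_reads(mk(100), feats, g, min_overhang = 1)
  expect_equal(fc2$read_count[fc2$feature == "junction_5p_1"], 0)
  expect_equal(fc2$read_count[fc2$feature == "intron_1"], 1)  # still intersects
})

test_that("uniform tiling gives junction count L-1 and equal normalized densities", {
  g <- gene_model("g", "c", "+", data.frame(start = c(0, 500), end = c(400, 900)))
  feats <- derive_features(g, 21, 1)
  starts <- 0:(900 - 21)
  lib <- sirna_library(
    tibble::tibble(read_id = sprintf("t%d", starts), start = starts,
                   length = 21L, strand = "+"),
    total_reads = length(starts)
  )
  fc <- count_feature_reads(lib, feats, g, min_overhang = 1)
  expect_equal(fc$read_count[fc$feature == "junction_5p_1"], 20)
  expect_equal(fc$read_count[fc$feature == "junction_3p_1"], 20)
  # size normalization makes junction density equal exon density in the
  # uniform limit (edge exons have no overhang inflation)
  nc <- setNames(fc$normalized_coverage, fc$feature)
  expect_equal(nc[["junction_5p_1"]], nc[["exon_1"]])
  expect_true(is.na(nc[["junction_ee_1"]]))  # spliced axis: not counted here
  # an interior interval feature counts overlapping reads, inflating its
  # density by (size + L - 1)/size relative to the per-start densities
  expect_equal(nc[["intron_1"]], nc[["exon_1"]] * 1.2)
})

test_that("junction counts match exhaustive per-read boundary checks", {
  set.seed(9)
  for (rep in 1:10) {
    g <- random_locus(n_exons = sample(2:4, 1))$gene
    feats <- derive_features(g, 21, 1)
    aln <- random_alignments(150, g$tss, g$transcript_end)
    lib <- sirna_library(aln, 1e6)
    for (o in c(1, 3)) {
      fc <- count_feature_reads(lib, feats, g, min_overhang = o)
      jn <- dplyr::filter(fc, axis == "genomic", grepl("junction", feature))
      for (j in seq_len(nrow(jn))) {
        pos <- feats$pos[feats$feature == jn$feature[j]]
        brute <- sum(aln$start + o <= pos & aln$start + aln$length - o >= pos)
        expect_equal(jn$read_count[j], brute)
      }
    }
  }
})

test_that("spliced-axis junction counting excludes genomically mappable reads", {
  set.seed(10)
  loc <- random_locus(n_exons = 3, strand = "+")
  g <- loc$gene
  ref <- loc$reference
  cdna <- spliced_sequence(g, ref)
  feats <- derive_features(g)
  ee_pos <- feats$pos[feats$kind == "exon_exon"][1]
  # read straddling the first exon-exon boundary of the spliced transcript
  straddle <- substr(cdna, ee_pos - 9, ee_pos + 10)
  # read fully inside one exon: maps to both axes -> excluded
  exonic <- substr(cdna, 2, 21)
  counts <- count_spliced_junction_reads(c(straddle, exonic), g, ref)
  expect_equal(counts$read_count[1], 1)
  expect_equal(attr(counts, "n_excluded_genomic"), 1)
  # with exclusion disabled the exonic read is retained but still spans nothing
  counts2 <- count_spliced_junction_reads(c(straddle, exonic), g, ref,
                                          exclude_genomic = FALSE)
  expect_equal(counts2$read_count[1], 1)
  expect_gte(attr(counts2, "n_spliced_mapped"), 2)
})

test_that("libraries built from unspliced pre-mRNA yield zero spliced-junction reads", {
  sim <- simulate_sirna_library(library_size = 3e4, background_rate = 2,
                                induction_ratio = 8, seed = 21)
  locus_reads <- sim$reads[sim$reads$origin != "filler", ]
  counts <- count_spliced_junction_reads(locus_reads, sim$gene, sim$reference)
  expect_true(all(counts$read_count == 0))
})

test_that("compare_features matches a closed-form paired t computation", {
  set.seed(11)
  reps <- sprintf("rep%d", 1:4)
  a <- c(2, 2, 2, 2) + rnorm(4, sd = 0.2)
  b <- c(1, 1, 1, 1) + rnorm(4, sd = 0.2)
  fc <- dplyr::bind_rows(
    tibble::tibble(feature = "exon_1", normalized_coverage = a, replicate_id = reps),
    tibble::tibble(feature = "intron_1", normalized_coverage = b, replicate_id = reps)
  )
  res <- compare_features(fc, "exon_1", "intron_1")
  # textbook paired t: t = mean(d) / (sd(d)/sqrt(n)), two-sided p from t_{n-1}
  d <- a - b
  t_exp <- mean(d) / (sd(d) / 2)
  expect_equal(res$t_statistic, t_exp)
  expect_equal(res$p_value, 2 * pt(-abs(t_exp), df = 3))
  expect_equal(res$n_replicates, 4)
  expect_false(res$degenerate)

  # identical values in every replicate: degenerate variance flag
  fc0 <- dplyr::mutate(fc, normalized_coverage = rep(c(2, 1), each = 4))
  res0 <- compare_features(fc0, "exon_1", "intron_1")
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p_value))
  expect_equal(res0$mean_difference, 1)
  expect_error(compare_features(fc[c(1, 5), ], "exon_1", "intron_1"), "replicates")
})

test_that("a planted 2x depressed intron is detected across 4 replicates", {
  set.seed(12)
  reps <- sprintf("rep%d", 1:4)
  fc <- dplyr::bind_rows(
    tibble::tibble(feature = "exon_1", normalized_coverage = 2 * exp(rnorm(4, sd = 0.05)),
                   replicate_id = reps),
    tibble::tibble(feature = "intron_2", normalized_coverage = 1 * exp(rnorm(4, sd = 0.05)),
                   replicate_id = reps)
  )
  expect_lt(compare_features(fc, "exon_1", "intron_2")$p_value, 0.05)
})

test_that("enrichment_test is Pearson chi-square with an independent CDF oracle", {
  # identical row proportions: statistic 0, p = 1
  flat <- enrichment_test(10, 100, 5, 50)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(13)
  for (i in 1:10) {
    h1 <- sample(1:20, 1); n1 <- h1 + sample(1:30, 1)
    h2 <- sample(1:40, 1); n2 <- h2 + sample(1:80, 1)
    res <- enrichment_test(h1, n1, h2, n2)
    # closed-form Pearson statistic from expected counts
    tab <- matrix(c(h1, n1 - h1, h2, n2 - h2), 2, byrow = TRUE)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - exp_tab)^2 / exp_tab)
    expect_equal(res$statistic, stat)
    expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE))
    expect_equal(res$df, 1)
  }
  expect_error(enrichment_test(0, 10, 0, 20), "marginal")
})

test_that("Prp19-complex recovery is enriched in both table constructions", {
  # disjoint groups: 8/16 Prp19 members vs 18/122 other spliceosome components
  disjoint <- enrichment_test(8, 16, 18, 122)
  expect_lte(disjoint$p_value, 0.04)
  # as printed: 8/16 vs the spliceosome-wide totals 26/138
  printed <- enrichment_test(8, 16, 26, 138)
  expect_lte(printed$p_value, 0.04)
  expect_gt(disjoint$rate_1, disjoint$rate_2)
})
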