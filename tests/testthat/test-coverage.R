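make_lib <- function(aln, total = 1e6, ...) sirna_library(aln, total, ...)

test_that("a single read gives a 21-base block and a 5'-end spike", {
  g <- gene_model("g", "c", "+", data.frame(start = 0, end = 1000))
  aln <- tibble::tibble(read_id = "r1", start = 100L, length = 21L, strand = "+")
  tr <- build_coverage(make_lib(aln), g)
  expect_equal(sum(tr$rpm_sense > 0), 21)
  expect_equal(unique(tr$rpm_sense[tr$rpm_sense > 0]), 1.0)
  expect_equal(which(tr$end_sense > 0) - 1, 100)  # 5'-end spike at the start
  expect_equal(max(tr$end_sense), 1.0)
  expect_true(all(tr$rpm_antisense == 0))

  # same read labeled antisense: spike moves to its 3' end, which for a
  # plus-strand gene is the same (leftmost) genomic coordinate
  aln2 <- dplyr::mutate(aln, strand = "-")
  tr2 <- build_coverage(make_lib(aln2), g)
  expect_equal(which(tr2$end_antisense > 0) - 1, 100)
  expect_true(all(tr2$end_sense == 0))
})

test_that("minus-strand genes place end spikes at the rightmost coordinate", {
  g <- gene_model("g", "c", "-", data.frame(start = 0, end = 1000))
  aln <- tibble::tibble(read_id = "r1", start = 100L, length = 21L, strand = "-")
  tr <- build_coverage(make_lib(aln), g)  # sense read for a minus gene
  expect_equal(which(tr$end_sense > 0) - 1, 120)
})

test_that("coverage equals the brute-force per-base oracle on random read sets", {
  set.seed(5)
  for (rep in 1:10) {
    g <- random_locus()$gene
    aln <- random_alignments(200, g$tss, g$transcript_end)
    lib <- make_lib(aln, total = 1e6)
    tr <- build_coverage(lib, g)
    sense <- aln[aln$strand == g$strand, ]
    anti <- aln[aln$strand != g$strand, ]
    expect_equal(tr$rpm_sense, oracle_coverage(sense, g$tss, g$transcript_end))
    expect_equal(tr$rpm_antisense, oracle_coverage(anti, g$tss, g$transcript_end))
    # end-trace mass = number of reads wholly inside the window
    inside <- sense$start >= g$tss & sense$start + sense$length <= g$transcript_end
    expect_equal(sum(tr$end_sense) * lib$total_reads / 1e6, sum(inside))
  }
})

test_that("read-length filter and empty-library error behave as documented", {
  g <- gene_model("g", "c", "+", data.frame(start = 0, end = 200))
  aln <- tibble::tibble(read_id = c("a", "b"), start = c(10L, 50L),
                        length = c(21L, 30L), strand = "+")
  tr <- build_coverage(make_lib(aln), g)
  expect_equal(sum(tr$rpm_sense) * 1e6 / 1e6, 21)  # the 30-mer filtered out
  expect_error(build_coverage(sirna_library(aln[0, ], 0), g), "positive")
})

test_that("uniform coverage gives ratio 1 and zero downstream flags undefined", {
  g <- gene_model("g", "c", "+", data.frame(start = 0, end = 2000))
  cs <- cut_site(1000)
  # uniform 5 RPM/bp on both strands
  starts <- seq(0L, 2000L - 20L, by = 20L)
  aln <- tibble::tibble(
    read_id = sprintf("u%d", seq_along(starts)),
    start = starts, length = 20L,
    strand = "+"
  )
  lib <- make_lib(aln, total = 1e6)
  rr <- cut_ratio(build_coverage(lib, g), g, cs)
  expect_equal(rr$ratio[rr$strand_mode == "both"], 1.0)
  expect_true(all(rr$ratio_defined[rr$strand_mode != "antisense"]))

  # all reads upstream: downstream mean 0 -> flagged, never Inf
  up <- aln[aln$start + aln$length <= 950, ]
  rr2 <- cut_ratio(build_coverage(make_lib(up), g), g, cs)
  expect_false(rr2$ratio_defined[1])
  expect_true(is.na(rr2$ratio[1]))
})

test_that("the sgRNA exclusion zone is removed from both mean and divisor", {
  g <- gene_model("g", "c", "+", data.frame(start = 0, end = 2000))
  cs <- cut_site(1000)
  # huge artificial peak exactly on the protospacer
  peak <- tibble::tibble(read_id = sprintf("p%d", 1:500), start = 983L,
                         length = 20L, strand = "+")
  base <- tibble::tibble(read_id = sprintf("b%d", seq(0, 1980, 20)),
                         start = seq(0L, 1980L, 20L), length = 20L, strand = "+")
  rr <- cut_ratio(build_coverage(make_lib(dplyr::bind_rows(base, peak)), g), g, cs,
                  exclusion_pad = 5)
  expect_equal(rr$ratio[1], 1.0, tolerance = 0.05)
  n_excluded <- 2000 - rr$upstream_bases[1] - rr$downstream_bases[1]
  expect_equal(n_excluded, 20 + 2 * 5)
  expect_error(
    cut_ratio(build_coverage(make_lib(base), g), g, cut_site(2100)), "inside"
  )
})

test_that("RPM scaling is equivariant and upstream reads only raise the ratio", {
  set.seed(6)
  g <- gene_model("g", "c", "+", data.frame(start = 0, end = 2000))
  cs <- cut_site(1000)
  aln <- random_alignments(300, 0, 2000)
  lib1 <- make_lib(aln, total = 1e5)
  lib2 <- make_lib(dplyr::bind_rows(aln, dplyr::mutate(aln, read_id = paste0(read_id, "_dup"))),
                   total = 2e5)
  r1 <- cut_ratio(build_coverage(lib1, g), g, cs)
  r2 <- cut_ratio(build_coverage(lib2, g), g, cs)
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(r1$upstream_mean_rpm, r2$upstream_mean_rpm)

  # monotonicity: add upstream-only reads, keep the same denominator
  extra <- tibble::tibble(read_id = sprintf("e%d", 1:100),
                          start = sample(0:900, 100, replace = TRUE),
                          length = 21L, strand = "+")
  lib3 <- make_lib(dplyr::bind_rows(aln, extra), total = 1e5)
  r3 <- cut_ratio(build_coverage(lib3, g), g, cs)
  expect_gte(r3$ratio[1], r1$ratio[1])
})

test_that("bedGraph tracks round-trip losslessly", {
  set.seed(8)
  g <- gene_model("g", "chrT", "+", data.frame(start = 10, end = 400))
  aln <- random_alignments(80, 10, 400)
  lib <- make_lib(aln, total = 12345)
  tr <- build_coverage(lib, g)
  prefix <- tempfile()
  paths <- write_tracks(tr, prefix)
  expect_length(paths, 4)
  tr2 <- read_tracks(prefix, g, library_size = 12345)
  expect_equal(tr2$rpm_sense, tr$rpm_sense)
  expect_equal(tr2$rpm_antisense, tr$rpm_antisense)
  expect_equal(tr2$end_sense, tr$end_sense)
  expect_equal(tr2$end_antisense, tr$end_antisense)

  # empty trace -> valid bedGraph with zero data lines
  tr0 <- build_coverage(make_lib(aln[0, ], total = 10), g)
  p0 <- write_tracks(tr0, tempfile())
  expect_equal(length(readLines(p0[1])), 0)
})
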