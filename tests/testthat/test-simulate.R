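test_that("identical seed and config give byte-identical libraries", {
  a <- simulate_sirna_library(library_size = 5000, background_rate = 0.5,
                              induction_ratio = 3, seed = 34)
  b <- simulate_sirna_library(library_size = 5000, background_rate = 0.5,
                              induction_ratio = 3, seed = 34)
  expect_identical(a$reads, b$reads)
  expect_identical(a$reference, b$reference)
  c <- simulate_sirna_library(library_size = 5000, background_rate = 0.5,
                              induction_ratio = 3, seed = 35)
  expect_false(identical(a$reference, c$reference))
  # the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1)
  simulate_sirna_library(library_size = 1000, background_rate = 0.2,
                         induction_ratio = 2, seed = 36)
  expect_identical(runif(1), before)
})

test_that("the truth record and read origins are internally consistent", {
  sim <- simulate_sirna_library(library_size = 2e4, background_rate = 1,
                                induction_ratio = 5, sgRNA_peak_fraction = 0.05,
                                seed = 37)
  tr <- sim$truth
  expect_equal(nrow(sim$reads), tr$library_size)
  expect_equal(
    as.integer(table(sim$reads$origin)[c("background", "induced", "sgRNA", "filler")]),
    as.integer(c(tr$n_background, tr$n_induced, tr$n_spike, tr$n_filler))
  )
  expect_equal(tr$effective_ratio, 5)  # intron upstream of the default cut
  expect_equal(tr$seed, 37)
  # sgRNA reads are exact protospacer copies
  sg <- sim$reads$sequence[sim$reads$origin == "sgRNA"][1]
  expect_equal(sg, substring(sim$reference, sim$cut$protospacer_start + 1,
                             sim$cut$protospacer_end))
})

test_that("an infeasible induction ratio errors with the feasible bound", {
  expect_error(
    simulate_sirna_library(library_size = 1000, background_rate = 1,
                           induction_ratio = 50, seed = 38),
    "feasible bound"
  )
})

test_that("a null library estimates a ratio near 1 through the full pipeline", {
  sim <- simulate_sirna_library(library_size = 4e4, background_rate = 3,
                                induction_ratio = 1, seed = 39)
  lib <- map_reads(sim$reads, sim$reference, reference_name = sim$gene$chrom)
  rr <- cut_ratio(build_coverage(lib, sim$gene), sim$gene, sim$cut)
  expect_equal(rr$ratio[1], 1, tolerance = 0.1)
})

test_that("cuts without an upstream intron are damped; intron-containing cuts are not", {
  damped <- simulate_sirna_library(intronless = TRUE, library_size = 3e4,
                                   background_rate = 1, induction_ratio = 50,
                                   seed = 40)
  expect_equal(damped$truth$effective_ratio, 1 + 49 * 0.04)
  # cut upstream of the first intron (first exon is 150 nt, intron at 150)
  pre <- simulate_sirna_library(cut_offset = 120, library_size = 3e4,
                                background_rate = 1, induction_ratio = 50,
                                seed = 41)
  expect_equal(pre$truth$effective_ratio, 1 + 49 * 0.04)
  post <- simulate_sirna_library(cut_offset = 1500, library_size = 1e5,
                                 background_rate = 1, induction_ratio = 50,
                                 seed = 42)
  expect_equal(post$truth$effective_ratio, 50)
})

test_that("minus-strand simulations recover the ratio in transcription orientation", {
  sim <- simulate_sirna_library(strand = "-", library_size = 5e4,
                                background_rate = 2, induction_ratio = 10,
                                seed = 43)
  lib <- map_reads(sim$reads, sim$reference, reference_name = sim$gene$chrom)
  rr <- cut_ratio(build_coverage(lib, sim$gene), sim$gene, sim$cut)
  expect_equal(rr$ratio[1], 10, tolerance = 0.15)
})

test_that("simulated libraries round-trip to disk in standard formats", {
  sim <- simulate_sirna_library(library_size = 2000, background_rate = 0.3,
                                induction_ratio = 2, seed = 44)
  dir <- tempfile()
  write_sirna_sim(sim, dir)
  reads <- read_fastq(file.path(dir, "reads.fastq"))
  expect_equal(reads$sequence, sim$reads$sequence)
  ref <- read_fastq(file.path(dir, "reference.fasta"), format = "fasta")
  expect_equal(ref$sequence, sim$reference)
  g <- read_gene_model(file.path(dir, "gene.gff3"), "simlocus")
  expect_equal(g$exons, sim$gene$exons)
  cuts <- read_cut_sites(file.path(dir, "cut_sites.tsv"))
  expect_equal(cuts$cut_position, sim$cut$cut_position)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, 44)
})

test_that("screen simulation is deterministic with well-formed plates", {
  a <- simulate_screen(n_plates = 2, n_replicates = 2, seed = 45)
  b <- simulate_screen(n_plates = 2, n_replicates = 2, seed = 45)
  expect_identical(a$wells, b$wells)
  w <- a$wells
  expect_equal(nrow(w), 2 * 2 * 384)
  expect_true(all(table(w$plate_id, w$replicate) == 384))
  # every plate carries all control classes
  per_plate <- table(w$annotation[w$replicate == 1], w$plate_id[w$replicate == 1])
  expect_true(all(per_plate["neg_ctrl", ] == 8))
  expect_true(all(per_plate["pos_ctrl", ] == 6))
  expect_true(all(per_plate["thread_ctrl", ] == 2))
  expect_true(all(w$fluc_raw > 0 & w$rluc_raw > 0))
})

test_that("positive and RLuc controls point in opposite directions", {
  sim <- simulate_screen(n_plates = 4, n_hits = 0, seed = 46)
  sc <- score_wells(normalize_plates(sim$wells))
  df <- tibble::as_tibble(sc)
  z_pos <- df$z[df$annotation == "pos_ctrl" & df$target_gene %in% c("Ago2", "Dcr-2")]
  z_rluc <- df$z[df$annotation == "rluc_ctrl"]
  expect_gt(min(z_pos), 3)    # strong de-repression of RLuc
  expect_lt(max(z_rluc), -3)  # direct RLuc knockdown suppresses the reporter
})

test_that("LOESS residuals are uncorrelated with FLuc despite channel coupling", {
  sim <- simulate_screen(n_plates = 6, n_hits = 0, rluc_fluc_exponent = 0.8,
                         seed = 47)
  sc <- score_wells(normalize_plates(sim$wells))
  smp <- dplyr::filter(tibble::as_tibble(sc), annotation == "sample")
  expect_lt(abs(cor(smp$resi, smp$fluc_norm)), 0.1)
  # raw channels were genuinely coupled before detrending
  expect_gt(cor(smp$fluc_norm, smp$rluc_norm), 0.3)
})

test_that("qPCR simulation is deterministic and honors zero noise", {
  a <- simulate_qpcr(seed = 48)
  b <- simulate_qpcr(seed = 48)
  expect_identical(a$ct, b$ct)
  z <- simulate_qpcr(noise_sd = 0, seed = 49)
  base <- z$ct[z$ct$condition == "uncut" & z$ct$amplicon == "exon_internal", ]
  expect_equal(unique(base$ct), 19.5)
})
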