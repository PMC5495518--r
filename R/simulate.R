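# Seeded generators for every input the analyses consume: break-induced
# small-RNA libraries from a parameterized locus, 384-well dual-luciferase
# screen plates with controls and spiked hits, and qPCR Ct tables with planted
# fold changes. Each simulator returns its full configuration as a truth
# record so recovery tests can compare estimates against ground truth.

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# n random sequences of length w, as a character vector
random_reads <- function(n, w) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * w, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a break-induced small-RNA sequencing library
#'
#' Models the siRNA response to a cas9 cut as a piecewise-uniform read source:
#' a uniform background of reads over the whole transcript, an induced zone
#' between the transcription start site and the cut where per-base density is
#' `induction_ratio` times the background, a read peak of sgRNA-derived
#' sequences at the protospacer, and off-locus filler reads (random sequences)
#' padding the library to `library_size`. Sense reads are drawn from the
#' unspliced pre-mRNA sequence and antisense reads from its reverse
#' complement, so no read can span an exon-exon junction on the spliced axis.
#' When the region between TSS and cut contains no complete intron (an
#' intron-less gene, or a cut upstream of the first intron), the induced
#' excess is damped by `intronless_damping`, reproducing the near-background
#' ratios seen when splicing cannot stimulate the response.
#'
#' @param exon_lengths,intron_lengths Transcript layout in bases
#'   (`length(intron_lengths) == length(exon_lengths) - 1`); defaults emulate
#'   a locus with a short first exon, a short first intron and a long second
#'   exon.
#' @param intronless If TRUE the gene is a single exon of the summed length.
#' @param strand Gene strand on the simulated reference.
#' @param cut_offset Cut position, bases 3' of the TSS along the genomic axis
#'   (in transcription orientation).
#' @param induction_ratio Target upstream/downstream per-base density ratio
#'   (>= 1) before damping.
#' @param sgRNA_peak_fraction Fraction of the library that is sgRNA-derived
#'   protospacer sequence.
#' @param background_rate Expected background reads per read-start position.
#' @param read_length Read length (default 21 nt).
#' @param library_size Total reads in the library (denominator for RPM).
#' @param flank Reference bases added on each side of the transcript.
#' @param intronless_damping Multiplier on the induced excess when no spliced
#'   intron lies upstream of the cut (default 0.04, which reproduces
#'   low-single-digit ratios at induction strengths that otherwise give
#'   ratios of several tens).
#' @param gene_id,chrom Identifiers for the simulated locus.
#' @param seed Integer seed; identical seed and configuration give identical
#'   output.
#' @return An object of class `sirna_sim`: list with `reads` (tibble
#'   `read_id`, `sequence`, `quality`), `reference` (character), `gene`
#'   ([gene_model()]), `cut` ([cut_site()]) and `truth` (list of all
#'   parameters plus realized counts and `effective_ratio`).
#' @export
simulate_sirna_library <- function(exon_lengths = c(150L, 2375L, 300L),
                                   intron_lengths = c(60L, 70L),
                                   intronless = FALSE,
                                   strand = "+",
                                   cut_offset = 1500L,
                                   induction_ratio = 10,
                                   sgRNA_peak_fraction = 0.02,
                                   background_rate = 5,
                                   read_length = 21L,
                                   library_size = 1e6,
                                   flank = 100L,
                                   intronless_damping = 0.04,
                                   gene_id = "simlocus", chrom = "simlocus",
                                   seed = 1L) {
  induction_ratio <- assert_number(induction_ratio, "induction_ratio", min = 1)
  sgRNA_peak_fraction <- assert_number(sgRNA_peak_fraction, "sgRNA_peak_fraction", 0, 1)
  background_rate <- assert_number(background_rate, "background_rate", min = 0)
  read_length <- assert_count(read_length, "read_length", 15L)
  library_size <- assert_count(library_size, "library_size", 1L)

  if (intronless) {
    exon_lengths <- sum(exon_lengths) + sum(intron_lengths)
    intron_lengths <- integer()
  }
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    abort("need exactly one intron length per internal exon boundary")
  }
  # build exon intervals left-to-right; for '-' the transcription order is
  # reversed but the genomic layout is the same
  starts <- flank + c(0L, cumsum(head(exon_lengths, -1L) + intron_lengths))
  exons <- tibble(start = as.integer(starts),
                  end = as.integer(starts + exon_lengths))
  g <- gene_model(gene_id, chrom, strand, exons)
  span <- gene_span_length(g)
  ref_len <- span + 2L * flank
  cut_pos <- if (strand == "+") g$tss + cut_offset else g$transcript_end - cut_offset
  if (cut_pos <= g$tss || cut_pos >= g$transcript_end) {
    abort("cut_offset places the cut outside the transcript")
  }
  cut <- if (strand == "+") cut_site(cut_pos, label = "sim_cut", chrom = chrom)
  else cut_site(cut_pos, cut_pos - 3L, cut_pos + 17L, label = "sim_cut", chrom = chrom)

  # start positions (0-based) of reads fully inside the transcript, and the
  # induced (TSS-to-cut) subset in transcription orientation
  all_starts <- seq.int(g$tss, g$transcript_end - read_length)
  up_starts <- if (strand == "+") {
    seq.int(g$tss, cut_pos - read_length)
  } else {
    seq.int(cut_pos, g$transcript_end - read_length)
  }

  # splicing requirement: without a complete intron upstream of the cut the
  # induced excess is damped
  ins <- introns(g)
  has_up_intron <- if (strand == "+") {
    any(ins$start >= g$tss & ins$end <= cut_pos)
  } else {
    any(ins$start >= cut_pos & ins$end <= g$transcript_end)
  }
  damping <- if (has_up_intron) 1 else intronless_damping
  effective_ratio <- 1 + (induction_ratio - 1) * damping

  n_spike <- round(sgRNA_peak_fraction * library_size)
  n_background <- round(background_rate * length(all_starts))
  n_induced <- round((effective_ratio - 1) * background_rate * length(up_starts))
  n_locus <- n_spike + n_background + n_induced
  if (n_locus > library_size) {
    max_ratio <- 1 + (library_size - n_spike - n_background) /
      (background_rate * length(up_starts) * damping)
    abort(sprintf(
      "induction_ratio infeasible at this library size and background_rate; the feasible bound is %.2f",
      max_ratio
    ))
  }
  n_filler <- library_size - n_locus

  with_seed(seed, {
    reference <- random_dna(ref_len)

    bg_starts <- sample(all_starts, n_background, replace = TRUE)
    ind_starts <- sample(up_starts, n_induced, replace = TRUE)
    starts <- c(bg_starts, ind_starts)
    sense <- runif(length(starts)) < 0.5
    seqs <- substring(reference, starts + 1L, starts + read_length)
    seqs[!sense] <- revcomp(seqs[!sense])

    proto_seq <- substring(reference, cut$protospacer_start + 1L, cut$protospacer_end)
    spike_seqs <- rep(proto_seq, n_spike)
    filler_seqs <- random_reads(n_filler, read_length)

    all_seqs <- c(seqs, spike_seqs, filler_seqs)
    origin <- c(
      rep("background", n_background), rep("induced", n_induced),
      rep("sgRNA", n_spike), rep("filler", n_filler)
    )
    perm <- sample.int(length(all_seqs))
    reads <- tibble(
      read_id = sprintf("sim_%d", seq_along(all_seqs)),
      sequence = all_seqs[perm],
      quality = strrep("I", nchar(all_seqs[perm])),
      origin = origin[perm]
    )

    truth <- list(
      exon_lengths = as.integer(exon_lengths),
      intron_lengths = as.integer(intron_lengths),
      intronless = intronless, strand = strand,
      cut_position = cut_pos, induction_ratio = induction_ratio,
      effective_ratio = effective_ratio, damping_applied = damping,
      sgRNA_peak_fraction = sgRNA_peak_fraction,
      background_rate = background_rate, read_length = read_length,
      library_size = library_size,
      n_background = n_background, n_induced = n_induced,
      n_spike = n_spike, n_filler = n_filler, seed = seed
    )
    structure(
      list(reads = reads, reference = reference, gene = g, cut = cut, truth = truth),
      class = "sirna_sim"
    )
  })
}

#' @export
print.sirna_sim <- function(x, ...) {
  cat(sprintf(
    "<sirna_sim> %d reads (%d locus, %d filler), effective ratio %.2f, seed %d\n",
    nrow(x$reads), with(x$truth, n_background + n_induced + n_spike),
    x$truth$n_filler, x$truth$effective_ratio, x$truth$seed
  ))
  invisible(x)
}

#' Write a simulated siRNA library to disk
#'
#' Emits `reads.fastq`, `reference.fasta`, `gene.gff3`, `cut_sites.tsv` and
#' `truth.yaml` under `dir`.
#'
#' @param sim A [simulate_sirna_library()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sirna_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sirna_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(sim$reference, sim$gene$chrom)),
    file.path(dir, "reference.fasta")
  )
  write_gene_model(sim$gene, file.path(dir, "gene.gff3"), format = "gff3")
  write_cut_sites(list(sim$cut), file.path(dir, "cut_sites.tsv"))
  yaml::write_yaml(sim$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

# 384-well plate addresses: rows A-P, columns 1-24
plate_wells_384 <- function() {
  rows <- LETTERS[1:16]
  as.vector(outer(rows, 1:24, function(r, c) sprintf("%s%02d", r, c)))
}

#' Simulate a dual-luciferase RNAi screen
#'
#' Generates `n_plates` distinct 384-well plates, each measured in
#' `n_replicates` replicate plates that [normalize_plates()] averages. Each
#' plate carries positive controls (Ago2, Dcr-2, Ago1 knockdowns that
#' de-repress RLuc), negative controls (GFP, DsRed), an RLuc knockdown and
#' thread (dead-cell) wells; the remaining wells are sample genes. Channel
#' intensities are multiplicative: baseline x plate effect x well effect x
#' gene effect x lognormal noise, with RLuc coupled to FLuc through
#' `rluc_fluc_exponent` so the LOESS fit has a real trend to remove.
#'
#' Spiked hit genes multiply RLuc by `exp(hit_effect * well_noise_sd)` in
#' every replicate — an effect stated in per-measurement residual SD units.
#' Negative-control wells carry an extra lognormal component
#' (`neg_ctrl_extra_sd`, in the same units) that is consistent across
#' replicates, emulating the between-aliquot variability of control dsRNA
#' preparations; this is what makes the "negative-control mean + 1 SD"
#' threshold stricter than one null SD.
#'
#' @param n_plates Distinct plate layouts (default 10).
#' @param n_replicates Replicate measurements per plate (default 3).
#' @param n_hits Number of spiked positive hit genes (default 40).
#' @param hit_effect Spiked effect size in per-measurement residual SD units
#'   (default 3).
#' @param plate_effect_sd SD of the per-plate, per-channel log-scale effect.
#' @param well_noise_sd Per-measurement log-scale RLuc noise SD (the residual
#'   SD unit).
#' @param fluc_noise_sd Per-measurement log-scale FLuc noise SD; FLuc is the
#'   high-signal transfection channel and is measured more precisely than its
#'   biological spread (default 0.1).
#' @param fluc_well_sd SD of the per-well transfection/viability effect that
#'   drives FLuc spread.
#' @param rluc_fluc_exponent Power coupling RLuc baseline to the well effect.
#' @param neg_ctrl_extra_sd Extra negative-control well variability, in
#'   `well_noise_sd` units (default 1.2).
#' @param pos_ctrl_effect,ago1_effect RLuc de-repression of the strong
#'   (Ago2/Dcr-2) and weaker (Ago1) positive controls, in the same SD units.
#' @param rluc_ctrl_factor Multiplier on RLuc for the RLuc-knockdown control.
#' @param thread_factor Multiplier on both channels for thread (dead) wells.
#' @param fluc_baseline,rluc_baseline Baseline intensities (arbitrary units).
#' @param seed Integer seed.
#' @return List of class `screen_sim`: `wells` (long tibble ready for
#'   [normalize_plates()], including a `replicate` column) and `truth` (list
#'   with the spiked hit genes and all parameters).
#' @export
simulate_screen <- function(n_plates = 10L, n_replicates = 3L, n_hits = 40L,
                            hit_effect = 3, plate_effect_sd = 0.15,
                            well_noise_sd = 0.25, fluc_noise_sd = 0.1,
                            fluc_well_sd = 0.5,
                            rluc_fluc_exponent = 0.8, neg_ctrl_extra_sd = 1.2,
                            pos_ctrl_effect = 8, ago1_effect = 4,
                            rluc_ctrl_factor = 0.1, thread_factor = 0.02,
                            fluc_baseline = 1e5, rluc_baseline = 1e4,
                            seed = 1L) {
  n_plates <- assert_count(n_plates, "n_plates", 1L)
  n_replicates <- assert_count(n_replicates, "n_replicates", 1L)

  wells <- plate_wells_384()
  # fixed control layout: column 24 plus two wells of column 23
  ctrl_map <- c(
    A24 = "pos:Ago2", B24 = "pos:Ago2", C24 = "pos:Dcr-2", D24 = "pos:Dcr-2",
    E24 = "pos:Ago1", F24 = "pos:Ago1",
    G24 = "neg:GFP", H24 = "neg:GFP", I24 = "neg:GFP", J24 = "neg:GFP",
    K24 = "neg:DsRed", L24 = "neg:DsRed", M24 = "neg:DsRed", N24 = "neg:DsRed",
    O24 = "rluc:Renilla", P24 = "rluc:Renilla",
    A23 = "thread:thread", B23 = "thread:thread"
  )

  with_seed(seed, {
    layout <- purrr::map_dfr(seq_len(n_plates), function(p) {
      w <- tibble(plate_id = sprintf("plate_%02d", p), well = wells)
      role <- ctrl_map[w$well]
      ann <- dplyr::case_when(
        startsWith(role, "pos:") ~ "pos_ctrl",
        startsWith(role, "neg:") ~ "neg_ctrl",
        startsWith(role, "rluc:") ~ "rluc_ctrl",
        startsWith(role, "thread:") ~ "thread_ctrl",
        TRUE ~ "sample"
      )
      ann[is.na(role)] <- "sample"
      gene <- if_else(
        ann == "sample",
        sprintf("gene_%02d_%s", p, w$well),
        sub("^[a-z]+:", "", role)
      )
      mutate(w, annotation = ann, target_gene = gene)
    })

    sample_genes <- unique(layout$target_gene[layout$annotation == "sample"])
    n_hits <- min(n_hits, length(sample_genes))
    hit_genes <- sample(sample_genes, n_hits)

    sigma <- well_noise_sd
    # gene effects on RLuc (log scale), consistent across replicates
    gene_eff <- setNames(numeric(length(sample_genes)), sample_genes)
    gene_eff[hit_genes] <- hit_effect * sigma

    # per-well aliquot effect for negative controls, consistent across reps
    layout$neg_aliquot <- 0
    is_neg <- layout$annotation == "neg_ctrl"
    layout$neg_aliquot[is_neg] <- rnorm(sum(is_neg), 0, neg_ctrl_extra_sd * sigma)

    out <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      x <- layout
      x$replicate <- r
      # per-replicate per-well transfection effect
      e_f <- rnorm(nrow(x), 0, fluc_well_sd)
      plate_f <- rnorm(n_plates, 0, plate_effect_sd)[as.integer(factor(x$plate_id))]
      plate_r <- rnorm(n_plates, 0, plate_effect_sd)[as.integer(factor(x$plate_id))]
      log_eff <- dplyr::case_when(
        x$annotation == "sample" ~ unname(gene_eff[x$target_gene]),
        x$annotation == "pos_ctrl" & x$target_gene %in% c("Ago2", "Dcr-2") ~ pos_ctrl_effect * sigma,
        x$annotation == "pos_ctrl" ~ ago1_effect * sigma,
        x$annotation == "neg_ctrl" ~ x$neg_aliquot,
        x$annotation == "rluc_ctrl" ~ log(rluc_ctrl_factor),
        TRUE ~ 0
      )
      dead <- x$annotation == "thread_ctrl"
      fluc <- fluc_baseline * exp(plate_f + e_f + rnorm(nrow(x), 0, fluc_noise_sd)) *
        if_else(dead, thread_factor, 1)
      rluc <- rluc_baseline * exp(plate_r + rluc_fluc_exponent * e_f + log_eff +
                                    rnorm(nrow(x), 0, sigma)) *
        if_else(dead, thread_factor, 1)
      mutate(x, fluc_raw = fluc, rluc_raw = rluc)
    })
    out <- select(out, "plate_id", "replicate", "well", "annotation",
                  "target_gene", "fluc_raw", "rluc_raw")

    truth <- list(
      hit_genes = sort(hit_genes), n_plates = n_plates,
      n_replicates = n_replicates, hit_effect = hit_effect,
      well_noise_sd = well_noise_sd, fluc_noise_sd = fluc_noise_sd,
      plate_effect_sd = plate_effect_sd,
      fluc_well_sd = fluc_well_sd, rluc_fluc_exponent = rluc_fluc_exponent,
      neg_ctrl_extra_sd = neg_ctrl_extra_sd, seed = seed,
      sample_genes = sample_genes
    )
    structure(list(wells = out, truth = truth), class = "screen_sim")
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Ct values are `baseline_ct[amplicon] - log2(fold) + N(0, noise_sd)` per
#' replicate, where `fold` is the planted fold change of that amplicon in
#' that condition (1 where unspecified). Defaults emulate a cut/uncut
#' experiment on a three-intron locus in which DNA cleavage increases nascent
#' (intron-exon junction) RNA 1.6-fold directly upstream of the break and
#' leaves spliced and total levels unchanged.
#'
#' @param baseline_ct Named numeric vector of baseline Ct per amplicon.
#' @param fold_changes Tibble `amplicon`, `condition`, `fold` of planted
#'   effects.
#' @param conditions Character vector of conditions to emit.
#' @param noise_sd Ct noise SD in cycles (default 0.1).
#' @param replicates Biological replicates per condition (default 3).
#' @param locus `target_locus` label.
#' @param seed Integer seed.
#' @return List of class `qpcr_sim`: `ct` (long tibble for [ddct()] etc.) and
#'   `truth`.
#' @export
simulate_qpcr <- function(baseline_ct = c(
                            intron_exon_junction_1 = 28, intron_exon_junction_2 = 28.5,
                            intron_exon_junction_3 = 28.2,
                            exon_exon_junction_1 = 20.5, exon_exon_junction_2 = 20.8,
                            exon_exon_junction_3 = 20.6,
                            exon_internal = 19.5
                          ),
                          fold_changes = tibble(
                            amplicon = "intron_exon_junction_3",
                            condition = "cut", fold = 1.6
                          ),
                          conditions = c("uncut", "cut"),
                          noise_sd = 0.1, replicates = 3L,
                          locus = "simlocus", seed = 1L) {
  noise_sd <- assert_number(noise_sd, "noise_sd", min = 0)
  replicates <- assert_count(replicates, "replicates", 1L)
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      amplicon = names(baseline_ct), condition = conditions,
      replicate = seq_len(replicates)
    )
    grid <- left_join(grid, fold_changes, by = c("amplicon", "condition"))
    grid$fold[is.na(grid$fold)] <- 1
    ct <- mutate(
      grid,
      sample_id = sprintf("%s_%s_r%d", locus, .data$condition, .data$replicate),
      target_locus = locus,
      ct = baseline_ct[.data$amplicon] - log2(.data$fold) +
        rnorm(n(), 0, noise_sd)
    )
    ct <- select(ct, "sample_id", "amplicon", "target_locus", "condition",
                 "replicate", "ct")
    truth <- list(
      baseline_ct = as.list(baseline_ct),
      fold_changes = as.data.frame(fold_changes),
      noise_sd = noise_sd, replicates = replicates, locus = locus, seed = seed
    )
    structure(list(ct = ct, truth = truth), class = "qpcr_sim")
  })
}
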