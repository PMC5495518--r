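# Configuration handling and stage runners tying the modules into
# reproducible runs: YAML config with defaults, unknown-key rejection, a
# single seed, and per-stage output directories with the resolved
# configuration echoed alongside the results.

#' Default analysis configuration
#'
#' One nested list with a block per stage (`simulate`, `map`, `coverage`,
#' `features`, `screen`, `qpcr`). [load_config()] merges a YAML file over
#' these defaults and rejects unknown keys.
#'
#' @return A named list of stage parameter lists.
#' @export
sirna_config <- function() {
  list(
    simulate = list(
      exon_lengths = c(150L, 2375L, 300L), intron_lengths = c(60L, 70L),
      intronless = FALSE, strand = "+", cut_offset = 1500L,
      induction_ratio = 10, sgRNA_peak_fraction = 0.02, background_rate = 5,
      read_length = 21L, library_size = 1e5, flank = 100L,
      intronless_damping = 0.04
    ),
    map = list(max_hits = 1L, adapter = NULL, min_overlap = 3L, min_len = 18L),
    coverage = list(read_length_min = 18L, read_length_max = 24L, exclusion_pad = 5L),
    features = list(read_length = 21L, min_overhang = 1L),
    screen = list(span = 0.9, degree = 2L, z_method = "standard", n_sd = 1),
    qpcr = list(cut_condition = "cut", uncut_condition = "uncut",
                ref_amplicon = "exon_internal")
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key: '%s'", here))
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) abort(sprintf("'%s' must be a mapping", here))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a YAML configuration over the package defaults
#'
#' @param path YAML file with any subset of the [sirna_config()] keys, or
#'   `NULL` for pure defaults.
#' @param overrides Optional named list applied on top of the file (highest
#'   precedence).
#' @return The resolved configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- sirna_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

write_resolved_config <- function(cfg, out_dir, stage, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    c(list(stage = stage, seed = seed), cfg),
    file.path(out_dir, "config_resolved.yaml")
  )
}

#' Run one pipeline stage
#'
#' Stages consume the conventional file names the previous stage wrote
#' (`reads.fastq`, `reference.fasta`, `gene.gff3`, `cut_sites.tsv`,
#' `alignments.bed`, `plates.tsv`, `ct.tsv`) from `in_dir` and write their
#' outputs plus the resolved configuration into `out_dir`.
#'
#' * `simulate` — write a seeded siRNA library simulation.
#' * `map` — FASTQ + FASTA -> `alignments.bed` + `map_stats.tsv`.
#' * `coverage` — alignments + gene + cut sites -> bedGraph tracks +
#'   `cut_ratio.tsv`.
#' * `features` — alignments + gene -> `feature_coverage.tsv`.
#' * `screen` — `plates.tsv` -> `screen_scores.tsv` + `screen_summary.tsv`.
#' * `qpcr` — `ct.tsv` -> `qpcr_folds.tsv`.
#' * `report` — joins whatever stage outputs exist in `in_dir` into
#'   `report.json`.
#'
#' @param stage One of `simulate`, `map`, `coverage`, `features`, `screen`,
#'   `qpcr`, `report`.
#' @param config A [sirna_config()]-shaped list (see [load_config()]).
#' @param in_dir Directory holding the stage inputs (not needed for
#'   `simulate`).
#' @param out_dir Output directory.
#' @param seed Integer seed for stages that draw random numbers.
#' @return A named list of output paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "map", "coverage", "features",
                                "screen", "qpcr", "report"),
                      config = sirna_config(), in_dir = NULL, out_dir,
                      seed = 1L) {
  stage <- match.arg(stage)
  write_resolved_config(config, out_dir, stage, seed)
  p <- function(dir, f) file.path(dir, f)
  out <- switch(
    stage,
    simulate = {
      sim <- do.call(simulate_sirna_library, c(config$simulate, list(seed = seed)))
      write_sirna_sim(sim, out_dir)
      list(dir = out_dir)
    },
    map = {
      reads <- read_fastq(p(in_dir, "reads.fastq"))
      ref <- read_fastq(p(in_dir, "reference.fasta"), format = "fasta")
      mc <- config$map
      if (!is.null(mc$adapter)) {
        reads <- trim_adapter(reads, mc$adapter, mc$min_overlap, mc$min_len)
      }
      lib <- map_reads(reads, ref$sequence[1L], max_hits = mc$max_hits,
                       reference_name = ref$read_id[1L])
      write_alignments(lib, p(out_dir, "alignments.bed"))
      readr::write_tsv(attr(lib, "map_stats"), p(out_dir, "map_stats.tsv"))
      list(alignments = p(out_dir, "alignments.bed"))
    },
    coverage = {
      g <- read_gene_model(p(in_dir, "gene.gff3"), find_gene_id(p(in_dir, "gene.gff3")))
      lib <- read_alignments(p(in_dir, "alignments.bed"), g$chrom,
                             total_reads = total_from_stats(in_dir))
      cuts <- cut_sites_from_table(read_cut_sites(p(in_dir, "cut_sites.tsv")))
      cc <- config$coverage
      trace <- build_coverage(lib, g, c(cc$read_length_min, cc$read_length_max))
      write_tracks(trace, p(out_dir, "trace"))
      ratios <- purrr::map_dfr(cuts, function(ct) {
        mutate(cut_ratio(trace, g, ct, cc$exclusion_pad), cut = ct$label, .before = 1L)
      })
      readr::write_tsv(ratios, p(out_dir, "cut_ratio.tsv"))
      list(cut_ratio = p(out_dir, "cut_ratio.tsv"))
    },
    features = {
      g <- read_gene_model(p(in_dir, "gene.gff3"), find_gene_id(p(in_dir, "gene.gff3")))
      lib <- read_alignments(p(in_dir, "alignments.bed"), g$chrom,
                             total_reads = total_from_stats(in_dir))
      fc <- config$features
      feats <- derive_features(g, fc$read_length, fc$min_overhang)
      res <- count_feature_reads(lib, feats, g, fc$min_overhang)
      readr::write_tsv(res, p(out_dir, "feature_coverage.tsv"))
      list(feature_coverage = p(out_dir, "feature_coverage.tsv"))
    },
    screen = {
      wells <- readr::read_tsv(p(in_dir, "plates.tsv"), show_col_types = FALSE)
      sc <- config$screen
      scores <- score_wells(
        normalize_plates(wells),
        span = sc$span, degree = sc$degree, z_method = sc$z_method,
        n_sd = sc$n_sd
      )
      readr::write_tsv(as_tibble(scores), p(out_dir, "screen_scores.tsv"))
      readr::write_tsv(glance(scores), p(out_dir, "screen_summary.tsv"))
      list(scores = p(out_dir, "screen_scores.tsv"))
    },
    qpcr = {
      ct <- read_ct_table(p(in_dir, "ct.tsv"))
      qc <- config$qpcr
      folds <- cut_uncut_ratio(ct, qc$cut_condition, qc$uncut_condition,
                               ref_amplicon = qc$ref_amplicon)
      readr::write_tsv(folds, p(out_dir, "qpcr_folds.tsv"))
      list(folds = p(out_dir, "qpcr_folds.tsv"))
    },
    report = {
      parts <- list()
      for (f in c("cut_ratio.tsv", "feature_coverage.tsv", "screen_summary.tsv",
                  "qpcr_folds.tsv")) {
        fp <- p(in_dir, f)
        if (file.exists(fp)) {
          parts[[sub("\\.tsv$", "", f)]] <- readr::read_tsv(fp, show_col_types = FALSE)
        }
      }
      jsonlite::write_json(parts, p(out_dir, "report.json"), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA)
      list(report = p(out_dir, "report.json"))
    }
  )
  invisible(out)
}

# helper: single gene id recorded in a pipeline gff3
find_gene_id <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- gr$ID[which(tolower(as.character(gr$type)) == "gene")]
  if (!length(ids)) abort(sprintf("no gene record in '%s'", path))
  as.character(ids[[1L]])
}

total_from_stats <- function(in_dir) {
  sp <- file.path(in_dir, "map_stats.tsv")
  if (file.exists(sp)) readr::read_tsv(sp, show_col_types = FALSE)$n_input[1L] else NULL
}
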