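# Dual-luciferase RNAi screen pipeline: per-channel log transform and
# plate-median normalization, replicate averaging, LOESS residual z-scores,
# control-derived candidate thresholds, dead-cell exclusion, 2-of-3 trigger
# validation and two-assay comparison.
#
# Sign convention: siRNAs generated at the break repress the Renilla (RLuc)
# reporter. Knocking down a factor *required* for siRNA biogenesis de-represses
# RLuc, i.e. lifts it above the fitted RLuc-on-FLuc curve: positive residual,
# positive z. Candidates promoting siRNA generation are therefore wells with z
# ABOVE the negative-control mean + 1 SD; repressor candidates sit below
# mean - 1 SD.

well_annotations <- c("sample", "pos_ctrl", "neg_ctrl", "rluc_ctrl",
                      "thread_ctrl", "empty")

#' Log-transform and plate-median normalize dual-luciferase plates
#'
#' Each channel is treated separately: values are log-transformed and the
#' median of the plate's *sample* wells is subtracted (thread, empty and
#' control wells do not move the median). Wells with non-positive raw values
#' are flagged invalid and dropped (counted in the `norm_stats` attribute).
#' When a `replicate` column is present, replicate plates are normalized
#' separately and then averaged per well, giving the mean normalized values
#' the downstream fit uses.
#'
#' @param wells Tibble with columns `plate_id`, `well`, `fluc_raw`,
#'   `rluc_raw`, `annotation` (one of `sample`, `pos_ctrl`, `neg_ctrl`,
#'   `rluc_ctrl`, `thread_ctrl`, `empty`), `target_gene`, and optionally
#'   `replicate`.
#' @param log_base Base of the log transform (default `exp(1)`; the choice
#'   only rescales both channels uniformly and median centering removes the
#'   shift).
#' @param collapse_replicates Average replicate plates per well (default TRUE).
#' @return Tibble with `plate_id`, `well`, `annotation`, `target_gene`,
#'   `fluc_norm`, `rluc_norm` (and `n_replicates` when collapsed).
#' @export
normalize_plates <- function(wells, log_base = exp(1), collapse_replicates = TRUE) {
  need <- c("plate_id", "well", "fluc_raw", "rluc_raw", "annotation", "target_gene")
  miss <- setdiff(need, names(wells))
  if (length(miss)) abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  bad_ann <- setdiff(unique(wells$annotation), well_annotations)
  if (length(bad_ann)) abort(sprintf("unknown annotation(s): %s", paste(bad_ann, collapse = ", ")))
  if (!"replicate" %in% names(wells)) wells$replicate <- 1L

  usable <- filter(wells, .data$annotation != "empty")
  invalid <- !is.finite(usable$fluc_raw) | !is.finite(usable$rluc_raw) |
    usable$fluc_raw <= 0 | usable$rluc_raw <= 0
  n_invalid <- sum(invalid)
  usable <- usable[!invalid, , drop = FALSE]

  norm <- usable |>
    group_by(.data$plate_id, .data$replicate) |>
    mutate(
      fluc_norm = log(.data$fluc_raw, base = log_base) -
        median(log(.data$fluc_raw[.data$annotation == "sample"], base = log_base)),
      rluc_norm = log(.data$rluc_raw, base = log_base) -
        median(log(.data$rluc_raw[.data$annotation == "sample"], base = log_base))
    ) |>
    ungroup()

  if (collapse_replicates) {
    norm <- norm |>
      group_by(.data$plate_id, .data$well, .data$annotation, .data$target_gene) |>
      summarise(
        fluc_norm = mean(.data$fluc_norm), rluc_norm = mean(.data$rluc_norm),
        n_replicates = n(), .groups = "drop"
      )
  } else {
    norm <- select(norm, "plate_id", "replicate", "well", "annotation",
                   "target_gene", "fluc_norm", "rluc_norm")
  }
  attr(norm, "norm_stats") <- tibble(
    n_wells = nrow(wells), n_invalid = n_invalid, log_base = log_base
  )
  norm
}

#' LOESS-residual z-scores and candidate calls for a normalized screen
#'
#' Fits [loess_local()] of `rluc_norm` on `fluc_norm` over the sample wells
#' (controls are scored against the fitted curve but do not shape it, by
#' default), standardizes the residuals into z-scores using the sample-well
#' residual distribution, and calls candidates against thresholds placed at
#' the negative-control z mean +/- 1 negative-control z SD. Wells whose
#' `fluc_norm` falls below the mean of the thread-control wells (predominantly
#' dead cells) are excluded before fitting and scoring.
#'
#' @param norm Output of [normalize_plates()] (replicates collapsed).
#' @param span,degree LOESS parameters (defaults 0.9 and 2).
#' @param z_method `"standard"` (mean/SD) or `"robust"` (median/MAD).
#' @param include_controls_in_fit Include control wells in the LOESS fit
#'   (default FALSE).
#' @param dead_cell_filter Apply the thread-derived FLuc floor (default TRUE;
#'   skipped when no thread wells are present).
#' @param n_sd Width of the candidate threshold in negative-control SD units
#'   (default 1).
#' @return A tibble of class `screen_scores` with per-well `fluc_norm`,
#'   `rluc_norm`, `fitted`, `resi`, `z` and `call` (`positive_candidate`,
#'   `negative_candidate`, `none`); attributes `thresholds` (tibble),
#'   `fit` (the `loess_local` object) and `n_dead_excluded`.
#' @export
score_wells <- function(norm, span = 0.9, degree = 2L,
                        z_method = c("standard", "robust"),
                        include_controls_in_fit = FALSE,
                        dead_cell_filter = TRUE, n_sd = 1) {
  z_method <- match.arg(z_method)

  n_dead <- 0L
  if (dead_cell_filter && any(norm$annotation == "thread_ctrl")) {
    floor_fluc <- mean(norm$fluc_norm[norm$annotation == "thread_ctrl"])
    dead <- norm$annotation != "thread_ctrl" & norm$fluc_norm < floor_fluc
    n_dead <- sum(dead)
    norm <- norm[!dead, , drop = FALSE]
  }

  fit_rows <- if (include_controls_in_fit) {
    norm$annotation %in% c("sample", "pos_ctrl", "neg_ctrl", "rluc_ctrl")
  } else norm$annotation == "sample"
  fit <- loess_local(norm$fluc_norm[fit_rows], norm$rluc_norm[fit_rows],
                     span = span, degree = degree)

  out <- norm
  out$fitted <- NA_real_
  out$fitted[fit_rows] <- fit$fitted
  out$fitted[!fit_rows] <- predict(fit, norm$fluc_norm[!fit_rows])
  out$resi <- out$rluc_norm - out$fitted

  sample_resi <- out$resi[out$annotation == "sample"]
  if (z_method == "standard") {
    center <- mean(sample_resi); scale <- sd(sample_resi)
  } else {
    center <- median(sample_resi); scale <- mad(sample_resi)
  }
  if (!is.finite(scale) || scale == 0) abort("residual scale is zero; cannot standardize")
  out$z <- (out$resi - center) / scale

  neg_z <- out$z[out$annotation == "neg_ctrl"]
  if (!length(neg_z)) abort("no negative-control wells present")
  up_thr <- mean(neg_z) + n_sd * sd(neg_z)
  lo_thr <- mean(neg_z) - n_sd * sd(neg_z)
  out$call <- dplyr::case_when(
    out$annotation != "sample" ~ "none",
    out$z > up_thr ~ "positive_candidate",
    out$z < lo_thr ~ "negative_candidate",
    TRUE ~ "none"
  )
  attr(out, "thresholds") <- tibble(
    upper = up_thr, lower = lo_thr,
    neg_ctrl_mean = mean(neg_z), neg_ctrl_sd = sd(neg_z),
    n_sd = n_sd, z_method = z_method
  )
  attr(out, "fit") <- fit
  attr(out, "n_dead_excluded") <- n_dead
  class(out) <- c("screen_scores", class(out))
  out
}

#' Apply the 2-of-3 trigger rule and counter-screen filter to candidates
#'
#' A candidate gene is retained only if at least two of its three independent
#' RNAi triggers (the screened dsRNA plus two non-overlapping validation
#' constructs) score positive, and the miR-277 counter-screen shows the core
#' silencing pathway and reporter transcription are unaffected
#' (`counter_screen == "specific"`).
#'
#' @param records Tibble with columns `target_gene`, `trigger_1`, `trigger_2`,
#'   `trigger_3` (each `"positive"`/`"negative"`, `NA` = missing) and
#'   `counter_screen` (`"specific"` or `"core_pathway_or_transcription"`).
#' @return The input with `n_triggers_positive`, `final_call`
#'   (`retained`/`dropped`/`incomplete`) and `failed_rule`
#'   (`NA`, `triggers`, `counter_screen`, or `missing_trigger`).
#' @export
validate_candidates <- function(records) {
  trig <- as.matrix(records[, c("trigger_1", "trigger_2", "trigger_3")])
  incomplete <- rowSums(is.na(trig)) > 0L
  n_pos <- rowSums(trig == "positive", na.rm = TRUE)
  pass_trig <- !incomplete & n_pos >= 2L
  pass_cs <- records$counter_screen == "specific"
  mutate(
    as_tibble(records),
    n_triggers_positive = n_pos,
    final_call = dplyr::case_when(
      incomplete ~ "incomplete",
      pass_trig & pass_cs ~ "retained",
      TRUE ~ "dropped"
    ),
    failed_rule = dplyr::case_when(
      incomplete ~ "missing_trigger",
      !pass_trig ~ "triggers",
      !pass_cs ~ "counter_screen",
      TRUE ~ NA_character_
    )
  )
}

#' Join per-gene effect strengths from two screens and classify overlap
#'
#' Used to compare DSB-induced siRNA effects with high-copy-transgene siRNA
#' effects: genes above the positive threshold in both assays are shared
#' machinery, genes above it in only one are assay-specific.
#'
#' @param scores_a,scores_b `screen_scores` tibbles (sample wells are used).
#' @param groups Optional tibble `target_gene`, `group` for labeling (e.g.
#'   splicing / repair / RfC).
#' @param suffix Length-2 suffix for the joined columns.
#' @return Tibble with per-gene `z` in both assays and `class`
#'   (`shared`, `a_specific`, `b_specific`, `neither`).
#' @export
compare_screens <- function(scores_a, scores_b, groups = NULL,
                            suffix = c("_a", "_b")) {
  thr_a <- attr(scores_a, "thresholds")$upper
  thr_b <- attr(scores_b, "thresholds")$upper
  a <- filter(as_tibble(scores_a), .data$annotation == "sample")
  b <- filter(as_tibble(scores_b), .data$annotation == "sample")
  j <- inner_join(
    select(a, "target_gene", "z", "call"),
    select(b, "target_gene", "z", "call"),
    by = "target_gene", suffix = suffix
  )
  if (nrow(j) == 0L) abort("no overlapping genes between the two screens")
  za <- j[[paste0("z", suffix[1L])]]
  zb <- j[[paste0("z", suffix[2L])]]
  j$class <- dplyr::case_when(
    za > thr_a & zb > thr_b ~ "shared",
    za > thr_a ~ "a_specific",
    zb > thr_b ~ "b_specific",
    TRUE ~ "neither"
  )
  if (!is.null(groups)) j <- left_join(j, groups, by = "target_gene")
  j
}

#' @rdname score_wells
#' @param x A `screen_scores` object.
#' @param ... Unused.
#' @export
glance.screen_scores <- function(x, ...) {
  thr <- attr(x, "thresholds")
  smp <- filter(as_tibble(x), .data$annotation == "sample")
  tibble(
    n_sample_wells = nrow(smp),
    n_positive = sum(smp$call == "positive_candidate"),
    n_negative = sum(smp$call == "negative_candidate"),
    upper_threshold = thr$upper, lower_threshold = thr$lower,
    n_dead_excluded = attr(x, "n_dead_excluded")
  )
}
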