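# Relative quantification of qPCR Ct tables by the 2^-ddCt method, splicing
# efficiency per amplicon class, and cut/uncut fold changes. Amplicon classes:
# intron_exon_junction amplicons detect unspliced pre-mRNA, exon_exon_junction
# amplicons detect spliced message, exon_internal amplicons detect total
# transcript and serve as the reference.

ct_required_cols <- c("sample_id", "amplicon", "target_locus", "condition",
                      "replicate", "ct")

check_ct <- function(ct) {
  miss <- setdiff(ct_required_cols, names(ct))
  if (length(miss)) abort(sprintf("Ct table lacks column(s): %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(ct$ct))) abort("all Ct values must be finite")
  as_tibble(ct)
}

#' Read a long-format qPCR Ct table
#'
#' @param path TSV/CSV with columns `sample_id`, `amplicon`, `target_locus`,
#'   `condition`, `replicate`, `ct`.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE)
  } else readr::read_tsv(path, show_col_types = FALSE)
  check_ct(df)
}

# per-replicate delta-Ct (target minus reference) for one condition
delta_ct <- function(ct, cond, target_amplicon, ref_amplicon, locus = NULL) {
  x <- filter(ct, .data$condition == cond)
  if (!is.null(locus)) x <- filter(x, .data$target_locus == locus)
  tgt <- filter(x, .data$amplicon == target_amplicon)
  ref <- filter(x, .data$amplicon == ref_amplicon)
  if (nrow(tgt) == 0L) abort(sprintf("no '%s' measurements for condition '%s'", target_amplicon, cond))
  if (nrow(ref) == 0L) abort(sprintf("no '%s' measurements for condition '%s'", ref_amplicon, cond))
  j <- inner_join(
    summarise(group_by(tgt, .data$replicate), ct_target = mean(.data$ct), .groups = "drop"),
    summarise(group_by(ref, .data$replicate), ct_ref = mean(.data$ct), .groups = "drop"),
    by = "replicate"
  )
  if (nrow(j) == 0L) abort("no replicate indices shared between target and reference amplicon")
  mutate(j, dct = .data$ct_target - .data$ct_ref)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Computes, per replicate, dCt = Ct(target) - Ct(reference) in the test and
#' control conditions, ddCt = dCt(test) - dCt(control), and the fold change
#' 2^-ddCt; replicates (matched by index) are then summarized as mean +/- SD
#' of the fold changes. Amplification efficiency is fixed at 2 per cycle.
#'
#' @param ct Long-format Ct tibble (see [read_ct_table()]).
#' @param test_condition,control_condition Condition labels.
#' @param target_amplicon Amplicon quantified.
#' @param ref_amplicon Reference amplicon (default `"exon_internal"`).
#' @param locus Optional `target_locus` filter.
#' @return One-row tibble: `fold_change` (mean of per-replicate 2^-ddCt),
#'   `ddct` (mean), `sd` (SD of fold changes), `n` (replicates), `p_value`
#'   (two-sided one-sample t-test of ddCt against 0; `NA` when n < 2 or the
#'   ddCt values are constant).
#' @export
ddct <- function(ct, test_condition, control_condition, target_amplicon,
                 ref_amplicon = "exon_internal", locus = NULL) {
  ct <- check_ct(ct)
  d_test <- delta_ct(ct, test_condition, target_amplicon, ref_amplicon, locus)
  d_ctrl <- delta_ct(ct, control_condition, target_amplicon, ref_amplicon, locus)
  j <- inner_join(d_test, d_ctrl, by = "replicate", suffix = c("_test", "_ctrl"))
  if (nrow(j) == 0L) {
    # unmatched replicate indices: fall back to condition means
    j <- tibble(ddct = mean(d_test$dct) - mean(d_ctrl$dct))
  } else {
    j <- mutate(j, ddct = .data$dct_test - .data$dct_ctrl)
  }
  folds <- 2^(-j$ddct)
  n <- length(folds)
  p <- if (n >= 2L && stats::var(j$ddct) > 0) {
    t.test(j$ddct, mu = 0, alternative = "two.sided")$p.value
  } else NA_real_
  tibble(
    target_amplicon = target_amplicon, ref_amplicon = ref_amplicon,
    test_condition = test_condition, control_condition = control_condition,
    fold_change = mean(folds), ddct = mean(j$ddct),
    sd = if (n >= 2L) sd(folds) else NA_real_, n = n, p_value = p
  )
}

#' Splicing efficiency: pre-mRNA and spliced message relative to total
#'
#' For one locus and condition, every intron-exon-junction amplicon yields the
#' relative unspliced pre-mRNA level `2^-(Ct_pre - Ct_total)` and every
#' exon-exon-junction amplicon the relative spliced level
#' `2^-(Ct_spliced - Ct_total)`, with the exon-internal amplicon as the
#' total-transcript reference. Values near 1 mean the species is as abundant
#' as total transcript; efficient splicing gives pre-mRNA values << 1.
#'
#' @param ct Long-format Ct tibble.
#' @param locus `target_locus` to analyse.
#' @param cond Condition label.
#' @param ref_amplicon Reference amplicon (default `"exon_internal"`).
#' @return Tibble, one row per non-reference amplicon: `amplicon`, `class`
#'   (`pre_mrna` for intron-exon, `spliced` for exon-exon, `other`),
#'   `rel_level` (mean over replicates), `sd`, `n`.
#' @export
splicing_efficiency <- function(ct, locus, cond, ref_amplicon = "exon_internal") {
  ct <- check_ct(ct)
  x <- filter(ct, .data$target_locus == locus, .data$condition == cond)
  if (!any(x$amplicon == ref_amplicon)) {
    abort(sprintf("no '%s' amplicon for locus '%s', condition '%s'", ref_amplicon, locus, cond))
  }
  amps <- setdiff(unique(x$amplicon), ref_amplicon)
  purrr::map_dfr(amps, function(a) {
    d <- delta_ct(x, cond, a, ref_amplicon)
    lv <- 2^(-d$dct)
    tibble(
      target_locus = locus, condition = cond, amplicon = a,
      class = dplyr::case_when(
        grepl("intron_exon", a) ~ "pre_mrna",
        grepl("exon_exon", a) ~ "spliced",
        TRUE ~ "other"
      ),
      rel_level = mean(lv), sd = if (length(lv) >= 2L) sd(lv) else NA_real_,
      n = length(lv)
    )
  })
}

#' Cut versus uncut fold changes per amplicon
#'
#' For each amplicon, computes the ddCt fold change of the cut condition over
#' the uncut condition, both normalized to the exon-internal amplicon, so only
#' DNA-break-induced changes remain (shared knockdown or batch effects cancel).
#'
#' @param ct Long-format Ct tibble.
#' @param cut_condition,uncut_condition Condition labels (defaults `"cut"`,
#'   `"uncut"`).
#' @param amplicons Amplicons to report (default: all non-reference amplicons
#'   present in the cut condition).
#' @param ref_amplicon Reference amplicon.
#' @param locus Optional `target_locus` filter.
#' @return Tibble, one row per amplicon, with the [ddct()] columns.
#' @export
cut_uncut_ratio <- function(ct, cut_condition = "cut", uncut_condition = "uncut",
                            amplicons = NULL, ref_amplicon = "exon_internal",
                            locus = NULL) {
  ct <- check_ct(ct)
  if (is.null(amplicons)) {
    x <- filter(ct, .data$condition == cut_condition)
    if (!is.null(locus)) x <- filter(x, .data$target_locus == locus)
    amplicons <- setdiff(unique(x$amplicon), ref_amplicon)
  }
  purrr::map_dfr(amplicons, function(a) {
    mutate(
      ddct(ct, cut_condition, uncut_condition, a, ref_amplicon, locus),
      amplicon = a, .before = 1L
    )
  })
}
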