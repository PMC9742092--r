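# Significance filters for the three evidence layers. All inequalities are
# strict, exactly as the rules are stated: boundary rows (|log2FC| equal to
# the threshold, |dPSI| = 0.05, CLIP fold change = 4) are excluded. Rows
# with missing statistics are excluded from the kept set but counted in the
# totals and reported via a message.

#' Significance thresholds for the three evidence layers
#'
#' Defaults implement the study-style rules: differential expression keeps
#' rows with p < .05 and |log2FC| > log2(1) = 0 (i.e. any non-zero fold
#' change at p < .05; the raw p-value, not the adjusted one, is tested);
#' differential splicing keeps events with |dPSI| > .05, p < .05 and
#' FDR < .1; CLIP peaks are kept at p < 1e-3 and fold enrichment > 4. All
#' comparisons are strict.
#'
#' @param deg_p DEG p-value cutoff (kept if p < `deg_p`).
#' @param deg_abs_log2fc DEG |log2 fold change| cutoff (kept if strictly
#'   greater).
#' @param as_abs_dpsi Splicing |dPSI| cutoff (strictly greater).
#' @param as_p Splicing p-value cutoff.
#' @param as_fdr Splicing FDR cutoff.
#' @param clip_p CLIP peak p-value cutoff.
#' @param clip_fc CLIP fold-enrichment cutoff (strictly greater).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(deg_p = 0.05, deg_abs_log2fc = log2(1),
                              as_abs_dpsi = 0.05, as_p = 0.05, as_fdr = 0.1,
                              clip_p = 1e-3, clip_fc = 4) {
  probs <- c(deg_p, as_p, as_fdr, clip_p)
  if (any(probs <= 0 | probs > 1)) {
    abort("Probability thresholds must lie in (0, 1]")
  }
  if (deg_abs_log2fc < 0 || as_abs_dpsi < 0 || clip_fc < 0) {
    abort("Fold-change thresholds must be >= 0")
  }
  structure(
    list(deg_p = deg_p, deg_abs_log2fc = deg_abs_log2fc,
         as_abs_dpsi = as_abs_dpsi, as_p = as_p, as_fdr = as_fdr,
         clip_p = clip_p, clip_fc = clip_fc),
    class = "filter_thresholds"
  )
}

note_na_rows <- function(n_na, what) {
  if (n_na > 0) {
    inform(paste0(n_na, " ", what,
                  " row(s) with missing statistics excluded from filtering"))
  }
}

#' Filter a differential-expression table
#'
#' Keeps rows with `pvalue < deg_p` and `|log2fc| > deg_abs_log2fc` (both
#' strict) and labels each survivor `"up"` (log2fc > 0) or `"down"`
#' (log2fc < 0). Under the default thresholds a log2fc of exactly 0 cannot
#' be kept, so the up/down partition is complete. Input row order is
#' preserved.
#'
#' @param deg Tibble from [read_deg_table()].
#' @param thresholds A [filter_thresholds()].
#' @return The kept rows with a `direction` column appended.
#' @export
filter_deg <- function(deg, thresholds = filter_thresholds()) {
  na_row <- is.na(deg$pvalue) | is.na(deg$log2fc)
  note_na_rows(sum(na_row), "differential-expression")
  keep <- !na_row & deg$pvalue < thresholds$deg_p &
    abs(deg$log2fc) > thresholds$deg_abs_log2fc
  deg[keep, , drop = FALSE] |>
    mutate(direction = if_else(.data$log2fc > 0, "up", "down"))
}

#' Filter a differential-splicing event table
#'
#' Keeps events with `|delta_psi| > as_abs_dpsi`, `pvalue < as_p` and
#' `fdr < as_fdr` (all strict) and labels each survivor `"inclusion_up"`
#' (dPSI > 0) or `"inclusion_down"` (dPSI < 0).
#'
#' @param events Tibble from [read_rmats_table()] or [read_rmats_bundle()].
#' @inheritParams filter_deg
#' @return The kept rows with a `direction` column appended.
#' @export
filter_as <- function(events, thresholds = filter_thresholds()) {
  na_row <- is.na(events$pvalue) | is.na(events$fdr) | is.na(events$delta_psi)
  note_na_rows(sum(na_row), "differential-splicing")
  keep <- !na_row &
    abs(events$delta_psi) > thresholds$as_abs_dpsi &
    events$pvalue < thresholds$as_p &
    events$fdr < thresholds$as_fdr
  events[keep, , drop = FALSE] |>
    mutate(direction = if_else(.data$delta_psi > 0,
                               "inclusion_up", "inclusion_down"))
}

#' Filter CLIP peaks on IP-vs-input enrichment
#'
#' Keeps peaks with p < `clip_p` (equivalently `neg_log10_p >
#' -log10(clip_p)`) and `fold_enrichment > clip_fc`, both strict: a peak at
#' exactly 4-fold enrichment is excluded. Refuses ChIP peak tables, for
#' which no score filter is applied in this pipeline.
#'
#' @param peaks Tibble from [read_narrowpeak()] with `assay = "clip"`.
#' @inheritParams filter_deg
#' @return The kept peak rows.
#' @export
filter_clip_peaks <- function(peaks, thresholds = filter_thresholds()) {
  if (!all(peaks$assay == "clip")) {
    abort("filter_clip_peaks() expects CLIP peaks (assay == \"clip\")")
  }
  na_row <- is.na(peaks$neg_log10_p) | is.na(peaks$fold_enrichment)
  note_na_rows(sum(na_row), "CLIP peak")
  keep <- !na_row &
    peaks$neg_log10_p > -log10(thresholds$clip_p) &
    peaks$fold_enrichment > thresholds$clip_fc
  peaks[keep, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction, for completing splicing tables
#' whose dialect lacks an FDR column. Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
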