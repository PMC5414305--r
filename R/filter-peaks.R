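#' Filter peaks on FDR q-value
#'
#' Retains peaks whose enrichment q-value is at most `alpha`. Peak files
#' carry `-log10(q)`, so the test is `neglog10_qvalue >= -log10(alpha)`.
#' Peaks with no q-value (ENCODE `-1` sentinel, stored as `NA`) cannot pass
#' an FDR filter and are dropped unless `keep_unscored = TRUE`.
#'
#' @param peaks A peak tibble.
#' @param alpha FDR threshold in (0, 1]; default 0.05.
#' @param keep_unscored Keep peaks whose q-value is unavailable?
#' @return The filtered peak tibble.
#' @export
filter_by_fdr <- function(peaks, alpha = 0.05, keep_unscored = FALSE) {
  assert_scalar_number(alpha, "alpha", min = .Machine$double.xmin, max = 1)
  thr <- -log10(alpha)
  keep <- !is.na(peaks$neglog10_qvalue) & peaks$neglog10_qvalue >= thr
  if (keep_unscored) keep <- keep | is.na(peaks$neglog10_qvalue)
  peaks[keep, ]
}

#' Filter CAGE peaks on tpm expression
#'
#' By default (`min_tpm_exclusive = NULL`) all CAGE peaks are used. A
#' numeric threshold retains only peaks expressed strictly above it, e.g.
#' `min_tpm_exclusive = 0` keeps peaks with tpm > 0.
#'
#' @param peaks A CAGE peak tibble.
#' @param min_tpm_exclusive `NULL` (keep all) or a tpm value; peaks must
#'   exceed it strictly.
#' @return The filtered peak tibble.
#' @export
filter_by_tpm <- function(peaks, min_tpm_exclusive = NULL) {
  if (nrow(peaks) > 0 && !all(peaks$assay == "CAGE")) {
    abort("filter_by_tpm() applies to CAGE peaks only", class = "zipperplot_config_error")
  }
  if (is.null(min_tpm_exclusive)) return(peaks)
  assert_scalar_number(min_tpm_exclusive, "min_tpm_exclusive", min = 0)
  peaks[!is.na(peaks$tpm) & peaks$tpm > min_tpm_exclusive, ]
}
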