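#' Zipper Height
#'
#' ZH is the fraction of features whose closest peak overlaps the TSS
#' (distance 0). Features with no eligible peak on their chromosome count in
#' the denominator but can never overlap, so ZH is in `[0, 1]` with 1 the
#' fully "closed zipper".
#'
#' @param hits A hit tibble from [batch_query()].
#' @return A single number in `[0, 1]`.
#' @export
zipper_height <- function(hits) {
  if (nrow(hits) == 0L) {
    abort("zipper_height() requires at least one hit", class = "zipperplot_config_error")
  }
  sum(!is.na(hits$distance) & hits$distance == 0) / nrow(hits)
}

#' Area Under the Zipper
#'
#' Each feature contributes a unit-height rectangle spanning from its TSS to
#' the nearest edge of its closest peak, i.e. `|distance|` nt, so
#' `auz_global` is the sum of unsigned distances. Because peaks can sit
#' asymmetrically around TSSs, the upstream (`auz_left`, distance < 0) and
#' downstream (`auz_right`, distance > 0) components are also reported;
#' `auz_global = auz_left + auz_right` always. Missing hits contribute
#' nothing here and are counted in `n_missing`. AUZ = 0 is the closed
#' zipper: every closest peak overlaps its TSS.
#'
#' @param hits A hit tibble.
#' @return A one-row tibble: `auz_global`, `auz_left`, `auz_right`,
#'   `n_features`, `n_missing`.
#' @export
auz <- function(hits) {
  d <- hits$distance
  tibble(auz_global = sum(abs(d[!is.na(d)])),
         auz_left = sum(abs(d[!is.na(d) & d < 0])),
         auz_right = sum(d[!is.na(d) & d > 0]),
         n_features = nrow(hits),
         n_missing = sum(is.na(d)))
}

#' Window-clipped Area Under the Zipper
#'
#' AUZ recomputed after virtually setting every distance larger than the
#' visualization half-window `w` (default 5000 nt) to `w`, so zippers drawn
#' with the same window are directly comparable. A missing hit behaves like
#' a peak beyond the window: it contributes `w`, split evenly between the
#' left and right components.
#'
#' @param hits A hit tibble.
#' @param w Window half-width in nt (> 0).
#' @return A one-row tibble: `auz_window`, `auz_window_left`,
#'   `auz_window_right`, `window_halfwidth`.
#' @export
auz_window <- function(hits, w = 5000) {
  assert_scalar_number(w, "w", min = .Machine$double.xmin)
  d <- hits$distance
  clipped <- pmin(abs(d), w)
  n_missing <- sum(is.na(d))
  left <- sum(clipped[!is.na(d) & d < 0]) + n_missing * w / 2
  right <- sum(clipped[!is.na(d) & d > 0]) + n_missing * w / 2
  tibble(auz_window = sum(clipped[!is.na(d)]) + n_missing * w,
         auz_window_left = left, auz_window_right = right,
         window_halfwidth = w)
}

#' All zipper summary statistics for one run
#'
#' Bundles [zipper_height()], [auz()] and [auz_window()]; permutation
#' p-values can be attached by [auz_permutation_test()] via the `test`
#' argument.
#'
#' @param hits A hit tibble.
#' @param w Window half-width in nt.
#' @param test Optionally, an `auz_test` from [auz_permutation_test()] whose
#'   p-values are folded into the result.
#' @return A `zipper_stats` object (a list); use [tidy()] or [glance()] for
#'   tibble views.
#' @export
zipper_stats <- function(hits, w = 5000, test = NULL) {
  a <- auz(hits)
  aw <- auz_window(hits, w)
  out <- structure(c(list(zh = zipper_height(hits)), as.list(a), as.list(aw),
                     list(auz_pval = NA_real_, auz_pval_left = NA_real_,
                          auz_pval_right = NA_real_, reps = NA_integer_,
                          seed = NA_integer_)),
                   class = "zipper_stats")
  if (!is.null(test)) {
    out$auz_pval <- test$pval
    out$auz_pval_left <- test$pval_left
    out$auz_pval_right <- test$pval_right
    out$reps <- test$reps
    out$seed <- test$seed
  }
  out
}

#' @export
print.zipper_stats <- function(x, ...) {
  cat(sprintf("<zipper_stats> %d features (%d missing)\n", x$n_features, x$n_missing))
  cat(sprintf("  ZH = %s | AUZ_global = %s (left %s, right %s)\n",
              fmt_num(x$zh), fmt_num(x$auz_global), fmt_num(x$auz_left),
              fmt_num(x$auz_right)))
  cat(sprintf("  AUZ_window(+/-%g nt) = %s (left %s, right %s)\n",
              x$window_halfwidth, fmt_num(x$auz_window),
              fmt_num(x$auz_window_left), fmt_num(x$auz_window_right)))
  if (!is.na(x$auz_pval)) {
    cat(sprintf("  AUZ_pval = %s (left %s, right %s; %d permutations)\n",
                fmt_num(x$auz_pval), fmt_num(x$auz_pval_left),
                fmt_num(x$auz_pval_right), x$reps))
  }
  invisible(x)
}

#' @rdname zipper_stats
#' @param x A `zipper_stats` object.
#' @param ... Unused.
#' @export
tidy.zipper_stats <- function(x, ...) {
  vals <- unclass(x)
  tibble(statistic = names(vals), value = as.numeric(unlist(vals)))
}

#' @rdname zipper_stats
#' @export
glance.zipper_stats <- function(x, ...) {
  as_tibble(lapply(unclass(x), function(v) v %||% NA))
}

#' Per-TSS cross-tissue p-value
#'
#' For features analysed in one chosen sample, asks how many samples in the
#' index have a peak as close (or closer) to the TSS than the chosen
#' sample's best peak, divided by the number of samples. The chosen sample
#' counts itself, so the smallest attainable value is `1/n_samples`; a
#' missing best distance counts as infinitely far.
#'
#' @param features A feature tibble.
#' @param index A `peak_index`.
#' @param chosen_sample The sample the user picked.
#' @return A tibble with `label` and `tss_pvalue`, one row per feature.
#' @export
per_tss_tissue_pvalue <- function(features, index, chosen_sample) {
  if (!chosen_sample %in% index$samples) {
    abort(sprintf("unknown sample_id '%s'", chosen_sample),
          class = "zipperplot_config_error")
  }
  dists <- vapply(index$samples, function(s) {
    d <- sample_nearest(index, features, s)$distance
    ifelse(is.na(d), Inf, abs(d))
  }, numeric(nrow(features)))
  dists <- matrix(dists, nrow = nrow(features))
  chosen <- dists[, match(chosen_sample, index$samples)]
  tibble(label = features$label,
         tss_pvalue = rowSums(dists <= chosen) / length(index$samples))
}
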