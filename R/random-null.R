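#' Read and merge exclusion regions
#'
#' Genomic regions that random TSSs must avoid — assembly gaps, centromeres,
#' telomeres, heterochromatin and repeats — supplied as one or more BED
#' files (first three columns used). Intervals are merged into a sorted,
#' non-overlapping set per chromosome.
#'
#' @param paths Character vector of BED file paths.
#' @return An exclusion tibble: `chrom`, `start`, `end` (0-based half-open),
#'   merged and sorted.
#' @export
read_exclusions <- function(paths) {
  beds <- map_dfr(paths, function(p) {
    df <- readr::read_tsv(p, col_names = FALSE, col_types = readr::cols(.default = "c"),
                          comment = "#", progress = FALSE)
    if (ncol(df) < 3L) {
      abort(sprintf("%s: BED needs at least 3 columns", p), class = "zipperplot_parse_error")
    }
    tibble(chrom = df[[1]], start = as.integer(df[[2]]), end = as.integer(df[[3]]))
  })
  merge_intervals(beds)
}

#' Merge an in-memory exclusion tibble
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Merged, sorted exclusion tibble.
#' @export
merge_exclusions <- function(regions) merge_intervals(regions)

# allowed 1-based positions on one chromosome: complement of excl within [1, len]
allowed_ranges <- function(excl, chrom, len) {
  m <- excl[excl$chrom == chrom, , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  # excluded 1-based bases are start+1 .. end
  lo <- c(1L, m$end + 1L)
  hi <- c(m$start, len)
  keep <- lo <= hi
  tibble(lo = lo[keep], hi = hi[keep])
}

#' Draw a blacklist-aware random TSS set
#'
#' Draws as many random TSS positions as the template has, preserving the
#' template's per-chromosome feature counts; positions are uniform over the
#' bases of each chromosome not covered by the exclusion set (cumulative
#' allowed-length inversion). With `preserve_strand = TRUE` (default) the
#' template's per-chromosome strand multiset is reused, which matters for
#' strand-matched CAGE queries; otherwise strands are uniform.
#'
#' @param template Feature tibble whose per-chromosome layout to mimic.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param exclusions Merged exclusion tibble (possibly empty).
#' @param seed Integer seed; the draw is a pure function of its inputs.
#' @param preserve_strand Copy per-chromosome strands from the template?
#' @return A feature tibble of random TSSs (`label` = `random_<n>`).
#' @export
sample_random_tss <- function(template, chrom_sizes, exclusions, seed,
                              preserve_strand = TRUE) {
  withr::with_seed(seed, {
    parts <- lapply(split(template, template$chrom), function(tt) {
      chrom <- tt$chrom[1]
      len <- chrom_sizes[[chrom]]
      if (is.null(len)) {
        abort(sprintf("template chromosome '%s' absent from chrom_sizes", chrom),
              class = "zipperplot_config_error")
      }
      rng <- allowed_ranges(exclusions, chrom, len)
      widths <- rng$hi - rng$lo + 1
      total <- sum(widths)
      if (total <= 0) {
        abort(sprintf("chromosome '%s' is fully excluded; cannot place random TSSs", chrom),
              class = "zipperplot_config_error")
      }
      k <- sample.int(total, nrow(tt), replace = TRUE)
      run <- findInterval(k, cumsum(c(1, widths[-length(widths)])))
      pos <- rng$lo[run] + (k - c(0, cumsum(widths))[run] - 1L)
      # strands sorted so the draw is invariant to the template's row order
      strand <- if (preserve_strand) sort(tt$strand) else
        sample(c("+", "-"), nrow(tt), replace = TRUE)
      feature_tibble(label = NA_character_, chrom = chrom, pos = pos, strand = strand)
    })
    out <- bind_rows(parts)
    out$label <- sprintf("random_%d", seq_len(nrow(out)))
    out
  })
}

#' Permutation test for the Area Under the Zipper
#'
#' Compares the observed AUZ against AUZ values from `reps` random TSS sets
#' drawn by [sample_random_tss()] and queried in the same mode as the
#' observed features. The one-sided p-value is the fraction of random sets
#' whose AUZ is smaller than or equal to the observed one — the chance that
#' a randomly placed feature set sits at least as close to peaks as the
#' user's set. Left and right p-values are computed the same way from the
#' sided AUZ components. By default the p-value is the plain quotient (so 0
#' is attainable); `pseudocount = TRUE` switches to `(k + 1) / (reps + 1)`.
#'
#' @param features The observed feature tibble.
#' @param index A `peak_index`.
#' @param exclusions Merged exclusion tibble.
#' @param mode,sample_id Query mode, as in [batch_query()].
#' @param reps Number of random zipper plots (default 100).
#' @param seed Integer seed driving all draws.
#' @param preserve_strand Passed to [sample_random_tss()].
#' @param pseudocount Use the `(k+1)/(R+1)` convention?
#' @param observed Optionally, the observed hit tibble (recomputed if
#'   omitted).
#' @return An `auz_test` object: observed AUZ components, `pval`,
#'   `pval_left`, `pval_right`, the tibble of null AUZ values, `reps`,
#'   `seed`.
#' @export
auz_permutation_test <- function(features, index, exclusions,
                                 mode = c("all_samples", "one_sample"),
                                 sample_id = NULL, reps = 100, seed = 1,
                                 preserve_strand = TRUE, pseudocount = FALSE,
                                 observed = NULL) {
  mode <- arg_match(mode)
  assert_scalar_number(reps, "reps", min = 1)
  if (is.null(observed)) {
    observed <- batch_query(features, index, mode = mode, sample_id = sample_id)
  }
  obs <- auz(observed)
  null_auz <- map_dfr(seq_len(reps), function(r) {
    rand <- sample_random_tss(features, index$chrom_sizes, exclusions,
                              seed = seed + r, preserve_strand = preserve_strand)
    d <- query_distances(rand, index, mode = mode, sample_id = sample_id)
    tibble(auz_global = sum(abs(d[!is.na(d)])),
           auz_left = sum(abs(d[!is.na(d) & d < 0])),
           auz_right = sum(d[!is.na(d) & d > 0]))
  })
  pv <- function(null, ob) {
    if (pseudocount) (sum(null <= ob) + 1) / (reps + 1) else sum(null <= ob) / reps
  }
  structure(list(observed = obs,
                 pval = pv(null_auz$auz_global, obs$auz_global),
                 pval_left = pv(null_auz$auz_left, obs$auz_left),
                 pval_right = pv(null_auz$auz_right, obs$auz_right),
                 null = null_auz, reps = as.integer(reps), seed = as.integer(seed)),
            class = "auz_test")
}

#' @export
print.auz_test <- function(x, ...) {
  cat(sprintf("<auz_test> observed AUZ_global = %s | p = %s (left %s, right %s) | %d permutations, seed %d\n",
              fmt_num(x$observed$auz_global), fmt_num(x$pval),
              fmt_num(x$pval_left), fmt_num(x$pval_right), x$reps, x$seed))
  invisible(x)
}

#' @rdname auz_permutation_test
#' @param x An `auz_test` object.
#' @param ... Unused.
#' @export
tidy.auz_test <- function(x, ...) {
  tibble(side = c("global", "left", "right"),
         observed = c(x$observed$auz_global, x$observed$auz_left, x$observed$auz_right),
         p.value = c(x$pval, x$pval_left, x$pval_right))
}

#' Convenience wrapper returning only the global AUZ p-value
#'
#' @inheritParams auz_permutation_test
#' @param observed_auz The observed global AUZ value being tested.
#' @return A single p-value in `[0, 1]`.
#' @export
auz_pvalue <- function(observed_auz, features, index, exclusions,
                       mode = c("all_samples", "one_sample"), sample_id = NULL,
                       reps = 100, seed = 1, preserve_strand = TRUE,
                       pseudocount = FALSE) {
  mode <- arg_match(mode)
  assert_scalar_number(reps, "reps", min = 1)
  null_auz <- vapply(seq_len(reps), function(r) {
    rand <- sample_random_tss(features, index$chrom_sizes, exclusions,
                              seed = seed + r, preserve_strand = preserve_strand)
    d <- query_distances(rand, index, mode = mode, sample_id = sample_id)
    sum(abs(d[!is.na(d)]))
  }, numeric(1))
  if (pseudocount) {
    (sum(null_auz <= observed_auz) + 1) / (reps + 1)
  } else {
    sum(null_auz <= observed_auz) / reps
  }
}
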