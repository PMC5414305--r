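#' Signed TSS-to-peak distance
#'
#' Computes the strand-aware signed distance between each feature and the
#' peak in the same row of `peaks`. The TSS coordinate is 1-based; peaks are
#' 0-based half-open, so the TSS occupies base `pos - 1` in peak
#' coordinates. The distance is 0 if and only if that base lies inside
#' `[start, end)`; otherwise it is the number of bases from the TSS to the
#' nearest peak base (an immediately adjacent peak is at distance 1). The
#' sign is positive when the peak lies downstream in feature orientation —
#' greater coordinates for a `+` feature, smaller coordinates for a `-`
#' feature — and negative when upstream.
#'
#' @param features Feature tibble (columns `chrom`, `pos`, `strand`), or one
#'   row per peak row.
#' @param peaks Peak tibble of the same height (columns `chrom`, `start`,
#'   `end`).
#' @return A numeric vector of signed distances in nt.
#' @export
signed_distance <- function(features, peaks) {
  if (nrow(features) != nrow(peaks)) {
    abort("features and peaks must have the same number of rows",
          class = "zipperplot_config_error")
  }
  if (!all(features$chrom == peaks$chrom)) {
    abort("signed_distance() requires feature and peak on the same chromosome",
          class = "zipperplot_config_error")
  }
  t <- features$pos - 1L
  gap <- ifelse(t < peaks$start, peaks$start - t,
                ifelse(t >= peaks$end, t - peaks$end + 1, 0))
  genome_side <- ifelse(t < peaks$start, 1L, ifelse(t >= peaks$end, -1L, 0L))
  orient <- ifelse(features$strand == "+", 1L, -1L)
  as.numeric(gap * genome_side * orient)
}

# distance-only query used in permutation loops, where the peak metadata
# of every null replicate would be discarded anyway
query_distances <- function(features, index, mode, sample_id = NULL) {
  if (mode == "one_sample") return(sample_nearest(index, features, sample_id)$distance)
  best <- rep(NA_real_, nrow(features))
  for (s in index$samples) {
    d <- sample_nearest(index, features, s)$distance
    better <- !is.na(d) & (is.na(best) | abs(d) < abs(best))
    best[better] <- d[better]
  }
  best
}

hit_tibble <- function(features, index, row, distance) {
  pk <- index$peaks[row, ]
  enrichment <- ifelse(pk$assay == "CAGE", pk$tpm, pk$signal_value)
  tibble(label = features$label, chrom = features$chrom, pos = features$pos,
         strand = features$strand,
         sample_id = pk$sample_id, assay = pk$assay,
         peak_start = pk$start, peak_end = pk$end, peak_strand = pk$strand,
         distance = distance,
         peak_width = pk$end - pk$start,
         enrichment = enrichment)
}

#' Closest peak to each TSS within one sample
#'
#' Binary-search retrieval of the peak minimising the unsigned signed
#' distance to each feature within `sample_id`. For CAGE indexes only peaks
#' on the feature's strand are eligible. Features on chromosomes without an
#' eligible peak get a missing hit (`NA` peak fields and distance). Ties at
#' equal distance prefer the downstream peak; among equal candidates the one
#' with the smaller start wins.
#'
#' @param features A feature tibble.
#' @param index A `peak_index`.
#' @param sample_id Sample to query.
#' @return A hit tibble, one row per feature in input order: feature fields
#'   plus `sample_id`, `assay`, `peak_start`, `peak_end`, `peak_strand`,
#'   `distance`, `peak_width`, `enrichment` (tpm for CAGE, signalValue
#'   otherwise).
#' @export
nearest_peak <- function(features, index, sample_id) {
  res <- sample_nearest(index, features, sample_id)
  out <- hit_tibble(features, index, res$row, res$distance)
  out$sample_id[is.na(res$row)] <- sample_id
  out$assay[is.na(res$row)] <- index$assay
  out
}

#' Closest peak to each TSS across all samples
#'
#' Runs [nearest_peak()] for every sample in the index and retains, per
#' feature, the sample whose best peak is closest (smallest unsigned
#' distance). Equal best distances across samples resolve to the
#' lexicographically smallest `sample_id`.
#'
#' @inheritParams nearest_peak
#' @return A hit tibble as in [nearest_peak()].
#' @export
nearest_across_samples <- function(features, index) {
  if (length(index$samples) == 0L) {
    abort("index holds no samples", class = "zipperplot_config_error")
  }
  best_row <- rep(NA_integer_, nrow(features))
  best_dist <- rep(NA_real_, nrow(features))
  best_sample <- rep(NA_character_, nrow(features))
  for (s in index$samples) {  # sorted: first strictly-better win = lexicographic tie rule
    res <- sample_nearest(index, features, s)
    better <- !is.na(res$distance) &
      (is.na(best_dist) | abs(res$distance) < abs(best_dist))
    best_row[better] <- res$row[better]
    best_dist[better] <- res$distance[better]
    best_sample[better] <- s
  }
  out <- hit_tibble(features, index, best_row, best_dist)
  out$sample_id <- best_sample
  out$assay[is.na(best_row)] <- index$assay
  out
}

#' Query a batch of features in one-sample or all-samples mode
#'
#' The two workflows of the method: either the user knows the tissue of
#' interest (`mode = "one_sample"`, with `sample_id`), or each feature is
#' analysed across every sample and the closest association is retained
#' (`mode = "all_samples"`).
#'
#' @inheritParams nearest_peak
#' @param mode `"one_sample"` or `"all_samples"`.
#' @param sample_id Required when `mode = "one_sample"`.
#' @return A hit tibble, one row per feature, input order preserved.
#' @export
batch_query <- function(features, index, mode = c("all_samples", "one_sample"),
                        sample_id = NULL) {
  mode <- arg_match(mode)
  if (nrow(features) == 0L) {
    abort("batch_query() requires at least one feature", class = "zipperplot_config_error")
  }
  if (mode == "one_sample") {
    if (is.null(sample_id)) {
      abort("mode 'one_sample' requires sample_id", class = "zipperplot_config_error")
    }
    nearest_peak(features, index, sample_id)
  } else {
    nearest_across_samples(features, index)
  }
}

#' Write a hit table to TSV
#'
#' @param hits A hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}
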