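#' Build a binary-searchable peak index
#'
#' Buckets peaks by sample and chromosome (and by strand for CAGE, whose
#' queries are strand-matched), sorts each bucket by start coordinate with
#' ties by end, and precomputes running-maximum end arrays so that the
#' nearest peak to any position is found in O(log n) even when peaks overlap
#' or nest. All peaks must come from a single assay; build one index per
#' assay.
#'
#' @param peaks A peak tibble (one assay).
#' @param chrom_sizes Named integer vector of chromosome lengths (nt).
#' @return A `peak_index` object.
#' @seealso [nearest_peak()], [batch_query()]
#' @export
build_index <- function(peaks, chrom_sizes) {
  if (nrow(peaks) > 0 && length(unique(peaks$assay)) != 1L) {
    abort("build_index() requires peaks from a single assay",
          class = "zipperplot_config_error")
  }
  assay <- if (nrow(peaks) > 0) peaks$assay[1] else NA_character_
  missing_chr <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(missing_chr) > 0) {
    abort(sprintf("peaks on chromosome(s) absent from chrom_sizes: %s",
                  paste(missing_chr, collapse = ", ")),
          class = "zipperplot_config_error")
  }
  too_long <- peaks$end > chrom_sizes[peaks$chrom]
  if (any(too_long)) {
    abort(sprintf("%d peak(s) extend beyond their chromosome length (first on %s)",
                  sum(too_long), peaks$chrom[which(too_long)[1]]),
          class = "zipperplot_config_error")
  }
  stranded <- identical(assay, "CAGE")
  sorted <- peaks |>
    mutate(.bucket_strand = if (stranded) .data$strand else "*") |>
    arrange(.data$sample_id, .data$chrom, .data$.bucket_strand, .data$start, .data$end) |>
    mutate(.row = row_number())
  keys <- paste(sorted$sample_id, sorted$chrom, sorted$.bucket_strand, sep = "\r")
  buckets <- lapply(split(seq_len(nrow(sorted)), keys), function(i) {
    e <- sorted$end[i]
    emax <- cummax(e)
    imp <- c(TRUE, emax[-1] > emax[-length(emax)])
    setter <- which(imp)
    earg <- setter[cumsum(imp)]  # bucket-local index attaining the running max end
    list(start = sorted$start[i], emax = emax, earg = earg, row = i)
  })
  structure(list(assay = assay, stranded = stranded,
                 chrom_sizes = chrom_sizes,
                 samples = sort(unique(sorted$sample_id)),
                 peaks = select(sorted, -".bucket_strand", -".row"),
                 buckets = buckets),
            class = "peak_index")
}

#' @export
print.peak_index <- function(x, ...) {
  cat(sprintf("<peak_index> assay: %s | %d peaks | %d sample(s) | %d chromosome(s)\n",
              x$assay %||% "(empty)", nrow(x$peaks), length(x$samples),
              length(x$chrom_sizes)))
  invisible(x)
}

#' Enumerate all peaks held by an index
#'
#' @param index A `peak_index`.
#' @return The peak tibble, sorted by sample, chromosome and start.
#' @export
index_peaks <- function(index) index$peaks

# Nearest peak within one (sample, chrom, strand-class) bucket for a vector
# of 0-based query positions t. Returns bucket-relative global row and the
# unsigned side (-1 upstream-in-genome/left, 0 overlap, +1 right).
bucket_nearest <- function(bucket, t, strand) {
  n <- length(bucket$start)
  j <- findInterval(t, bucket$start)           # last peak with start <= t
  i0 <- findInterval(t, bucket$emax) + 1L      # first peak whose running-max end > t
  covered <- i0 <= j & i0 <= n
  dl <- ifelse(j >= 1L, t - bucket$emax[pmax(j, 1L)] + 1, Inf)
  dr <- ifelse(j < n, bucket$start[pmin(j + 1L, n)] - t, Inf)
  # tie at equal gap: take the side downstream in feature orientation
  right_wins <- dr < dl | (dr == dl & strand == "+")
  pick <- ifelse(covered, 0L, ifelse(is.infinite(dl) & is.infinite(dr), NA_integer_,
                                     ifelse(right_wins, 1L, -1L)))
  local <- ifelse(is.na(pick), NA_integer_,
                  ifelse(pick == 0L, i0,
                         ifelse(pick == 1L, j + 1L, bucket$earg[pmax(j, 1L)])))
  gap <- ifelse(is.na(pick) | pick == 0L, 0, ifelse(pick == 1L, dr, dl))
  gap[is.na(pick)] <- NA_real_
  sign <- ifelse(pick == 0L, 0L, pick * ifelse(strand == "+", 1L, -1L))
  list(row = ifelse(is.na(local), NA_integer_, bucket$row[pmax(local, 1L)]),
       distance = sign * gap)
}

# Vectorized nearest-peak for one sample over a feature tibble.
# Returns tibble(row, distance) aligned with `features`.
sample_nearest <- function(index, features, sample_id) {
  if (!sample_id %in% index$samples) {
    abort(sprintf("unknown sample_id '%s' (index has: %s)", sample_id,
                  paste(index$samples, collapse = ", ")),
          class = "zipperplot_config_error")
  }
  row <- rep(NA_integer_, nrow(features))
  dist <- rep(NA_real_, nrow(features))
  strand_class <- if (index$stranded) features$strand else rep("*", nrow(features))
  keys <- paste(sample_id, features$chrom, strand_class, sep = "\r")
  for (k in unique(keys)) {
    sel <- which(keys == k)
    bucket <- index$buckets[[k]]
    if (is.null(bucket)) next
    res <- bucket_nearest(bucket, features$pos[sel] - 1L, features$strand[sel])
    row[sel] <- res$row
    dist[sel] <- res$distance
  }
  tibble(row = row, distance = dist)
}
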