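# Independent brute-force oracle for nearest-peak retrieval.
#
# Deliberately written from the distance definition alone (no binary search,
# no shared code with the index): for each feature, scan every peak on its
# chromosome (same strand only when `stranded`), compute the signed distance
# from first principles, and keep the minimum unsigned distance with the
# documented tie rules (downstream first, then smaller start, then smaller
# sample_id).
oracle_signed_distance <- function(pos, strand, start, end) {
  t <- pos - 1
  if (t >= start && t < end) return(0)
  gap <- if (t < start) start - t else t - end + 1
  genome_side <- if (t < start) 1 else -1
  orient <- if (strand == "+") 1 else -1
  gap * genome_side * orient
}

oracle_nearest <- function(feature, peaks, stranded = FALSE) {
  cand <- peaks[peaks$chrom == feature$chrom, , drop = FALSE]
  if (stranded) cand <- cand[cand$strand == feature$strand, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(distance = NA_real_, start = NA, end = NA,
                                    sample_id = NA_character_))
  d <- vapply(seq_len(nrow(cand)), function(i)
    oracle_signed_distance(feature$pos, feature$strand, cand$start[i], cand$end[i]),
    numeric(1))
  best <- abs(d) == min(abs(d))
  cand <- cand[best, , drop = FALSE]
  d <- d[best]
  ord <- order(-d, cand$start, cand$sample_id)  # downstream first, then smaller start
  list(distance = d[ord[1]], start = cand$start[ord[1]], end = cand$end[ord[1]],
       sample_id = cand$sample_id[ord[1]])
}

# random peak set with overlapping/nested intervals allowed
random_peaks <- function(n, chrom_sizes, n_samples = 1, assay = "DNase") {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  start <- vapply(chrom, function(ch) sample.int(chrom_sizes[[ch]] - 600L, 1L), integer(1))
  width <- sample.int(500L, n, replace = TRUE)
  strand <- if (assay == "CAGE") sample(c("+", "-"), n, replace = TRUE) else "*"
  zipperplot:::peak_tibble(
    chrom = chrom, start = start, end = start + width, strand = strand,
    signal_value = round(runif(n, 0.1, 30), 3),
    neglog10_qvalue = if (assay == "CAGE") NA_real_ else round(runif(n, 0, 6), 3),
    tpm = if (assay == "CAGE") round(runif(n, 0, 40), 3) else NA_real_,
    sample_id = sample(sprintf("s%d", seq_len(n_samples)), n, replace = TRUE),
    assay = assay)
}

random_features <- function(n, chrom_sizes) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  pos <- vapply(chrom, function(ch) sample.int(chrom_sizes[[ch]], 1L), integer(1))
  zipperplot:::feature_tibble(sprintf("f%d", seq_len(n)), chrom, pos,
                              sample(c("+", "-"), n, replace = TRUE))
}

hits_from_distances <- function(d) {
  tibble::tibble(label = sprintf("f%d", seq_along(d)), chrom = "chr1",
                 pos = 1000L + seq_along(d), strand = "+",
                 sample_id = "s1", assay = "DNase",
                 peak_start = 1L, peak_end = 2L, peak_strand = "*",
                 distance = d, peak_width = 100L,
                 enrichment = 1)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
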