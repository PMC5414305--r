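#' Read ENCODE peak files
#'
#' Parse ENCODE `narrowPeak` (BED6+4), `broadPeak` (BED6+3) and `gappedPeak`
#' (BED12+3) files into the package's peak tibble. ChIP-seq and DNase-seq
#' peaks are unstranded: the strand column of the file is ignored and peaks
#' are stored with strand `"*"`. The q-value column is the ENCODE convention
#' `-log10(q)`; the sentinel `-1` (no q-value available) is stored as `NA`.
#' For gappedPeak, the block structure is discarded and only the outer
#' `chromStart`/`chromEnd` interval is kept, since distance queries use the
#' peak edge closest to the TSS and never the blocks.
#'
#' Extra trailing columns are tolerated with a warning; missing required
#' columns are an error naming the offending line. Records with
#' `start >= end` or negative `start` are rejected with a warning.
#'
#' @param path Path to the peak file.
#' @param sample_id Sample-type identifier to attach to every peak.
#' @param assay Assay label, e.g. `"DNase"` or `"ChIP:H3K4me3"`. Must not be
#'   `"CAGE"`; CAGE peaks have their own dialect (see [read_cage_peaks()]).
#' @return A tibble with one row per peak: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `signal_value`, `neglog10_qvalue`, `tpm` (always
#'   `NA` here), `sample_id`, `assay`.
#' @seealso [read_cage_peaks()], [filter_by_fdr()], [build_index()]
#' @export
read_narrowpeak <- function(path, sample_id, assay = "ChIP") {
  read_encode_peaks(path, sample_id, assay, kind = "narrowPeak")
}

#' @rdname read_narrowpeak
#' @export
read_broadpeak <- function(path, sample_id, assay = "ChIP") {
  read_encode_peaks(path, sample_id, assay, kind = "broadPeak")
}

#' @rdname read_narrowpeak
#' @export
read_gappedpeak <- function(path, sample_id, assay = "ChIP") {
  read_encode_peaks(path, sample_id, assay, kind = "gappedPeak")
}

peak_tibble <- function(chrom = character(), start = integer(), end = integer(),
                        strand = character(), signal_value = double(),
                        neglog10_qvalue = double(), tpm = double(),
                        sample_id = character(), assay = character()) {
  tibble(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), strand = as.character(strand),
         signal_value = as.double(signal_value),
         neglog10_qvalue = as.double(neglog10_qvalue), tpm = as.double(tpm),
         sample_id = as.character(sample_id), assay = as.character(assay))
}

encode_dialects <- list(
  narrowPeak = list(ncol = 10L, signal = 7L, qval = 9L),
  broadPeak  = list(ncol = 9L,  signal = 7L, qval = 9L),
  gappedPeak = list(ncol = 15L, signal = 13L, qval = 15L)
)

read_encode_peaks <- function(path, sample_id, assay, kind) {
  if (identical(assay, "CAGE")) {
    abort("CAGE peaks use their own dialect; see read_cage_peaks()",
          class = "zipperplot_config_error")
  }
  d <- encode_dialects[[kind]]
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(peak_tibble())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc < d$ncol)) {
    i <- which(nc < d$ncol)[1]
    abort_parse(path, i, sprintf("expected >= %d tab-separated columns for %s, found %d",
                                 d$ncol, kind, nc[i]))
  }
  if (any(nc > d$ncol)) {
    warn(sprintf("%s: %d line(s) carry extra trailing columns (ignored)",
                 path, sum(nc > d$ncol)))
  }
  col <- function(j) vapply(fields, `[[`, character(1), j)
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(col(j)))
    if (anyNA(x)) abort_parse(path, which(is.na(x))[1], sprintf("non-numeric %s", what))
    x
  }
  start <- num(2L, "start")
  end <- num(3L, "end")
  if (kind == "gappedPeak") {
    nblocks <- num(10L, "blockCount")
    sizes <- strsplit(col(11L), ",", fixed = TRUE)
    if (any(lengths(sizes) != nblocks)) {
      warn(sprintf("%s: blockSizes/blockCount mismatch on %d line(s); outer interval used",
                   path, sum(lengths(sizes) != nblocks)))
    }
  }
  bad <- start >= end | start < 0
  if (any(bad)) {
    warn(sprintf("%s: %d record(s) rejected (start >= end or negative start)",
                 path, sum(bad)))
  }
  q <- num(d$qval, "qValue")
  q[q < 0] <- NA_real_  # ENCODE -1 sentinel: q-value unavailable
  out <- peak_tibble(chrom = col(1L), start = start, end = end, strand = "*",
                     signal_value = num(d$signal, "signalValue"),
                     neglog10_qvalue = q, tpm = NA_real_,
                     sample_id = sample_id, assay = assay)
  out[!bad, ]
}

#' Read a multi-sample CAGE peak table
#'
#' CAGE peaks are stranded TSS clusters with one tpm (tags per million)
#' expression value per sample. The expected dialect is tab-separated with a
#' header line `#chrom start end name score strand <sample_id> ...` and BED6
#' body rows followed by one numeric tpm column per sample. Each (interval,
#' sample) pair becomes one peak row, so a file with `k` sample columns
#' yields `k` peaks per interval.
#'
#' @param path Path to the CAGE peak table.
#' @return A peak tibble (see [read_narrowpeak()]) with `assay = "CAGE"`,
#'   strand `+`/`-` and per-sample `tpm` populated.
#' @export
read_cage_peaks <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], "#")) {
    abort(sprintf("%s: CAGE table must start with a '#chrom ...' header naming the samples", path),
          class = "zipperplot_parse_error")
  }
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 7L) {
    abort(sprintf("%s: CAGE table has no sample columns", path),
          class = "zipperplot_parse_error")
  }
  samples <- hdr[-(1:6)]
  body <- lines[-1]
  if (length(body) == 0L) return(peak_tibble())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nc <- lengths(fields)
  want <- 6L + length(samples)
  if (any(nc != want)) {
    i <- which(nc != want)[1]
    abort_parse(path, i + 1L, sprintf("expected %d columns, found %d", want, nc[i]))
  }
  col <- function(j) vapply(fields, `[[`, character(1), j)
  strand <- col(6L)
  if (!all(strand %in% c("+", "-"))) {
    i <- which(!strand %in% c("+", "-"))[1]
    abort_parse(path, i + 1L, "CAGE peaks must be stranded (+ or -)")
  }
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  if (anyNA(start) || anyNA(end)) {
    abort_parse(path, which(is.na(start) | is.na(end))[1] + 1L, "non-integer coordinate")
  }
  per_sample <- lapply(seq_along(samples), function(k) {
    tpm <- suppressWarnings(as.numeric(col(6L + k)))
    if (anyNA(tpm)) {
      abort_parse(path, which(is.na(tpm))[1] + 1L,
                  sprintf("non-numeric tpm in sample column '%s'", samples[k]))
    }
    peak_tibble(chrom = col(1L), start = start, end = end, strand = strand,
                signal_value = tpm, neglog10_qvalue = NA_real_, tpm = tpm,
                sample_id = samples[k], assay = "CAGE")
  })
  bind_rows(per_sample)
}

#' Write peaks back to their source dialect
#'
#' Inverse of the readers, used for round-trip checks and for materialising
#' synthetic scenarios. Fields the package does not model (name, score,
#' p-value, point source, blocks) are written as neutral placeholders.
#'
#' @param peaks A peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  q <- ifelse(is.na(peaks$neglog10_qvalue), -1, peaks$neglog10_qvalue)
  lines <- sprintf("%s\t%d\t%d\t.\t0\t.\t%g\t-1\t%g\t-1",
                   peaks$chrom, peaks$start, peaks$end, peaks$signal_value, q)
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
write_broadpeak <- function(peaks, path) {
  q <- ifelse(is.na(peaks$neglog10_qvalue), -1, peaks$neglog10_qvalue)
  lines <- sprintf("%s\t%d\t%d\t.\t0\t.\t%g\t-1\t%g",
                   peaks$chrom, peaks$start, peaks$end, peaks$signal_value, q)
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
write_cage_peaks <- function(peaks, path) {
  wide <- peaks |>
    select("chrom", "start", "end", "strand", "sample_id", "tpm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "tpm")
  samples <- setdiff(names(wide), c("chrom", "start", "end", "strand"))
  hdr <- paste(c("#chrom", "start", "end", "name", "score", "strand", samples),
               collapse = "\t")
  body <- paste(wide$chrom, wide$start, wide$end, ".", 0, wide$strand, sep = "\t")
  for (s in samples) body <- paste(body, wide[[s]], sep = "\t")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name and length in nt.
#'
#' @param path Path to the sizes file.
#' @return A named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = readr::cols(chrom = "c", size = "i"),
                        progress = FALSE)
  setNames(df$size, df$chrom)
}

#' Read a sample catalog
#'
#' One line per sample file: `sample_id`, `assay`, human-readable `name`,
#' `path`. Used by [cmd_build_db()] to assemble a database; replicate
#' collapsing is the catalog's responsibility (list one file per sample).
#'
#' @param path Path to the TSV catalog.
#' @return A tibble with columns `sample_id`, `assay`, `name`, `path`.
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(path, col_names = c("sample_id", "assay", "name", "path"),
                        col_types = "cccc", progress = FALSE)
  dup <- df |> group_by(.data$assay, .data$sample_id) |> filter(n() > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("catalog: duplicate sample_id within an assay: %s",
                  paste(unique(dup$sample_id), collapse = ", ")),
          class = "zipperplot_config_error")
  }
  df
}
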