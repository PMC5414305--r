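#' Read transcript models from BED12
#'
#' Each BED12 record becomes one transcript model with its exon blocks. The
#' biotype (protein-coding vs lncRNA) is conveyed by which file a model is
#' read from, so it is supplied as an argument. The 5' TSS and 3' end follow
#' the strand: on `+` the TSS is the smallest coordinate, on `-` the
#' largest.
#'
#' @param path Path to the BED12 file.
#' @param biotype `"protein_coding"` or `"lncRNA"`.
#' @return A model tibble: `transcript_id`, `gene_id`, `biotype`, `class`
#'   (`mono-exonic`/`multi-exonic`), `chrom`, `strand`, `tss`, `end3`
#'   (1-based), `n_exons` and a list-column `exons` of 0-based half-open
#'   exon tibbles.
#' @export
read_transcript_models_bed12 <- function(path, biotype = c("lncRNA", "protein_coding")) {
  biotype <- arg_match(biotype)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(model_tibble())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc < 12L)) {
    abort_parse(path, which(nc < 12L)[1], sprintf("BED12 needs 12 columns, found %d",
                                                  nc[which(nc < 12L)[1]]))
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    start <- as.integer(f[2]); end <- as.integer(f[3]); strand <- f[6]
    if (is.na(start) || is.na(end)) abort_parse(path, i, "non-integer coordinate")
    if (!strand %in% c("+", "-")) abort_parse(path, i, "transcript models must be stranded")
    nblk <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    offs <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != nblk || length(offs) != nblk) {
      abort_parse(path, i, "blockSizes/blockStarts do not match blockCount")
    }
    ex_start <- start + offs
    exons <- tibble(start = ex_start, end = ex_start + sizes)
    build_model(transcript_id = f[4], gene_id = f[4], biotype = biotype,
                chrom = f[1], strand = strand, exons = exons)
  })
  bind_rows(rows)
}

model_tibble <- function() {
  tibble(transcript_id = character(), gene_id = character(), biotype = character(),
         class = character(), chrom = character(), strand = character(),
         tss = integer(), end3 = integer(), n_exons = integer(), exons = list())
}

build_model <- function(transcript_id, gene_id, biotype, chrom, strand, exons) {
  exons <- arrange(exons, .data$start)
  if (any(exons$start >= exons$end) ||
      (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))) {
    abort(sprintf("transcript '%s': exons must be non-overlapping, sorted intervals",
                  transcript_id), class = "zipperplot_parse_error")
  }
  tibble(transcript_id = transcript_id, gene_id = gene_id, biotype = biotype,
         class = if (nrow(exons) == 1L) "mono-exonic" else "multi-exonic",
         chrom = chrom, strand = strand,
         tss = if (strand == "+") min(exons$start) + 1L else max(exons$end),
         end3 = if (strand == "+") max(exons$end) else min(exons$start) + 1L,
         n_exons = nrow(exons), exons = list(exons))
}

#' Read transcript models from a minimal GTF subset
#'
#' Only `exon` features are used; `gene_id`, `transcript_id` and a biotype
#' attribute (`biotype`, `gene_biotype` or `transcript_biotype`) are
#' required. Exons are grouped per transcript into one model each.
#'
#' @param path Path to the GTF file.
#' @return A model tibble as in [read_transcript_models_bed12()].
#' @export
read_transcript_models_gtf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "exon", logical(1))
  fields <- fields[keep]
  if (length(fields) == 0L) return(model_tibble())
  attr_of <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0(key, ' "([^"]*)"'))[, 2]
    m
  }
  df <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(vapply(fields, `[[`, character(1), 4)) - 1L,  # GTF is 1-based inclusive
    end = as.integer(vapply(fields, `[[`, character(1), 5)),
    strand = vapply(fields, `[[`, character(1), 7),
    attrs = vapply(fields, `[[`, character(1), 9))
  df$gene_id <- attr_of(df$attrs, "gene_id")
  df$transcript_id <- attr_of(df$attrs, "transcript_id")
  bt <- attr_of(df$attrs, "biotype")
  bt[is.na(bt)] <- attr_of(df$attrs, "gene_biotype")[is.na(bt)]
  bt[is.na(bt)] <- attr_of(df$attrs, "transcript_biotype")[is.na(bt)]
  df$biotype <- bt
  if (anyNA(df$transcript_id) || anyNA(df$gene_id) || anyNA(df$biotype)) {
    abort(sprintf("%s: exon records need gene_id, transcript_id and a biotype attribute", path),
          class = "zipperplot_parse_error")
  }
  parts <- split(df, df$transcript_id)
  bind_rows(lapply(parts, function(tt) {
    build_model(transcript_id = tt$transcript_id[1], gene_id = tt$gene_id[1],
                biotype = tt$biotype[1], chrom = tt$chrom[1], strand = tt$strand[1],
                exons = tibble(start = tt$start, end = tt$end))
  }))
}

#' Write transcript models to BED12
#'
#' @param models A model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_models_bed12 <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    start <- min(ex$start); end <- max(ex$end)
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            models$chrom[i], start, end, models$transcript_id[i], models$strand[i],
            start, end, nrow(ex),
            paste0(ex$end - ex$start, collapse = ","),
            paste0(ex$start - start, collapse = ","))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read splice junctions from BED12 (TopHat junctions.bed dialect)
#'
#' Each record is one junction: the two blocks are the aligned flanks on
#' either side of the splice, block sizes are the flank lengths, and the
#' score column is the number of supporting reads.
#'
#' @param path Path to the junction BED12 file.
#' @return A junction tibble: `name`, `chrom`, `strand`, `read_count`,
#'   0-based half-open flank intervals `left_start`, `left_end`,
#'   `right_start`, `right_end`, plus `donor_end` (last base of the left
#'   flank) and `acceptor_start` (first base of the right flank).
#' @export
read_junctions_bed12 <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) return(junction_tibble())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc < 12L)) {
    abort_parse(path, which(nc < 12L)[1], "junction records must be BED12")
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    start <- as.integer(f[2]); end <- as.integer(f[3])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    if (length(sizes) != 2L) abort_parse(path, i, "a junction record needs exactly 2 blocks")
    if (any(sizes < 1L)) abort_parse(path, i, "flank lengths must be >= 1")
    tibble(name = f[4], chrom = f[1], strand = f[6],
           read_count = as.numeric(f[5]),
           left_start = start, left_end = start + sizes[1],
           right_start = end - sizes[2], right_end = end)
  })
  out <- bind_rows(rows)
  if (any(out$left_end > out$right_start)) {
    abort_parse(path, which(out$left_end > out$right_start)[1],
                "junction flanks overlap (donor must precede acceptor)")
  }
  mutate(out, donor_end = .data$left_end - 1L, acceptor_start = .data$right_start)
}

junction_tibble <- function() {
  tibble(name = character(), chrom = character(), strand = character(),
         read_count = double(), left_start = integer(), left_end = integer(),
         right_start = integer(), right_end = integer(),
         donor_end = integer(), acceptor_start = integer())
}

#' Write junctions to the BED12 junction dialect
#'
#' @param junctions A junction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed12 <- function(junctions, path) {
  j <- junctions
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%d\t%d\t0\t2\t%d,%d\t%d,%d",
                   j$chrom, j$left_start, j$right_end, j$name, j$read_count, j$strand,
                   j$left_start, j$right_end,
                   j$left_end - j$left_start, j$right_end - j$right_start,
                   0L, j$right_start - j$left_start)
  readr::write_lines(lines, path)
  invisible(path)
}
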