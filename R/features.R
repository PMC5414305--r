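#' Read a TSS feature file
#'
#' One genomic feature per line, three tab-separated fields — chromosome,
#' 1-based genomic coordinate of the TSS, strand (`+`/`-`) — with an
#' optional fourth label column. Features without a label are named
#' `feature_<n>` by line order. Files larger than `max_features` lines are
#' rejected; the default cap of 20,000 features is configurable.
#'
#' @param path Path to the feature file.
#' @param max_features Maximum number of features accepted.
#' @return A tibble with columns `label`, `chrom`, `pos`, `strand`.
#' @export
read_features <- function(path, max_features = 20000) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > max_features) {
    abort(sprintf("feature file has %d features; the cap is %d (max_features)",
                  length(lines), max_features),
          class = "zipperplot_config_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc < 3L | nc > 4L)) {
    i <- which(nc < 3L | nc > 4L)[1]
    abort_parse(path, i, sprintf("expected 3 or 4 tab-separated fields, found %d", nc[i]))
  }
  col <- function(j) vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_,
                            character(1))
  pos <- suppressWarnings(as.integer(col(2L)))
  if (anyNA(pos)) abort_parse(path, which(is.na(pos))[1], "non-integer TSS coordinate")
  strand <- col(3L)
  if (!all(strand %in% c("+", "-"))) {
    abort_parse(path, which(!strand %in% c("+", "-"))[1],
                sprintf("strand must be '+' or '-', found '%s'",
                        strand[!strand %in% c("+", "-")][1]))
  }
  label <- col(4L)
  label[is.na(label)] <- sprintf("feature_%d", which(is.na(label)))
  feature_tibble(label = label, chrom = col(1L), pos = pos, strand = strand)
}

feature_tibble <- function(label = character(), chrom = character(),
                           pos = integer(), strand = character()) {
  tibble(label = as.character(label), chrom = as.character(chrom),
         pos = as.integer(pos), strand = as.character(strand))
}

#' Write features to the three/four-column TSV dialect
#'
#' @param features A feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_lines(paste(features$chrom, features$pos, features$strand,
                           features$label, sep = "\t"), path)
  invisible(path)
}
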