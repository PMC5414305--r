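`%||%` <- function(x, y) if (is.null(x)) y else x

abort_parse <- function(path, line, msg) {
  abort(sprintf("%s: line %d: %s", path, line, msg), class = "zipperplot_parse_error")
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
          class = "zipperplot_config_error")
  }
  invisible(x)
}

# merge possibly-overlapping 0-based half-open intervals, per chromosome
merge_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  df |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -1L))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("chrom", "start", "end")
}

# total nt covered by merged intervals within [0, len)
covered_length <- function(merged, chrom, len) {
  m <- merged[merged$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) return(0)
  sum(pmin(m$end, len) - pmax(m$start, 0L))
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", vapply(x, function(v) format(signif(v, digits)), character(1)))
}
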