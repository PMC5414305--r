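#' Rank hits for the zipper plot
#'
#' Stable sort by unsigned distance, so overlapping peaks sit at the top
#' (rank 1) and the zipper opens as peaks lie further away. Ties at equal
#' unsigned distance order by signed distance descending (downstream before
#' upstream), then by input order; missing hits rank last in input order.
#'
#' @param hits A hit tibble.
#' @return The hit tibble with a leading `rank` column, sorted by rank.
#' @export
rank_hits <- function(hits) {
  key <- abs(hits$distance)
  key[is.na(key)] <- Inf
  ord <- order(key, -hits$distance, seq_len(nrow(hits)), na.last = TRUE)
  out <- hits[ord, ]
  out$rank <- seq_len(nrow(out))
  select(out, "rank", dplyr::everything())
}

#' Drawable zipper geometry
#'
#' Converts ranked hits into TSS-relative segments: each peak is drawn from
#' its near edge (at the signed distance) extending by its width away from
#' the TSS, truncated at the window bounds. Rows whose near edge falls
#' outside `[-w, +w]` keep their rank but get no drawable extent, matching
#' the visual convention that peaks beyond the window exist but are not
#' displayed.
#'
#' @param ranked Output of [rank_hits()].
#' @param w Window half-width in nt (default 5000).
#' @return A `zipper_geometry` object: tibble `rows` (`rank`, `distance`,
#'   `x0`, `x1`, `enrichment`, `label`) plus `window_halfwidth`.
#' @export
build_geometry <- function(ranked, w = 5000) {
  assert_scalar_number(w, "w", min = .Machine$double.xmin)
  d <- ranked$distance
  width <- ranked$peak_width
  x0 <- ifelse(d >= 0, d, pmax(d - width + 1, -w))
  x1 <- ifelse(d >= 0, pmin(d + width - 1, w), d)
  drawable <- !is.na(d) & abs(d) <= w
  x0[!drawable] <- NA_real_
  x1[!drawable] <- NA_real_
  rows <- tibble(rank = ranked$rank, distance = d, x0 = x0, x1 = x1,
                 enrichment = ranked$enrichment, label = ranked$label)
  structure(list(rows = rows, window_halfwidth = w), class = "zipper_geometry")
}

#' @export
print.zipper_geometry <- function(x, ...) {
  cat(sprintf("<zipper_geometry> %d rows (%d drawable) | window +/-%g nt\n",
              nrow(x$rows), sum(!is.na(x$rows$x0)), x$window_halfwidth))
  invisible(x)
}

#' Zipper plot of a geometry
#'
#' A central vertical axis marks the TSS; each feature is one horizontal
#' segment at its rank (rank 1 on top), coloured by `log1p` enrichment (tpm
#' for CAGE, signalValue otherwise). ZH and AUZ annotations are added when
#' `stats` is supplied.
#'
#' @param object A `zipper_geometry`.
#' @param stats Optional `zipper_stats` to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zipper_geometry <- function(object, stats = NULL, ...) {
  w <- object$window_halfwidth
  rows <- filter(object$rows, !is.na(.data$x0))
  if (nrow(rows) == 0L) {
    abort("geometry has no drawable rows", class = "zipperplot_config_error")
  }
  subtitle <- NULL
  if (!is.null(stats)) {
    subtitle <- sprintf("ZH = %s | AUZ_global = %s | AUZ_window = %s%s",
                        fmt_num(stats$zh), fmt_num(stats$auz_global),
                        fmt_num(stats$auz_window),
                        if (!is.na(stats$auz_pval))
                          sprintf(" | AUZ_pval = %s", fmt_num(stats$auz_pval)) else "")
  }
  ggplot2::ggplot(rows) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$rank, yend = .data$rank,
                                       colour = log1p(.data$enrichment)),
                          linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "log1p(enrichment)") +
    ggplot2::coord_cartesian(xlim = c(-w, w)) +
    ggplot2::labs(x = "distance to TSS (nt)", y = "rank", subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.zipper_geometry
#' @export
plot_zipper <- function(object, stats = NULL, ...) autoplot.zipper_geometry(object, stats, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render a zipper plot to SVG or PNG
#'
#' Pure function of (geometry, stats): the same inputs produce identical
#' files. SVG via the cairo device, PNG via ragg when available.
#'
#' @param geom A `zipper_geometry`.
#' @param stats Optional `zipper_stats`.
#' @param path Output file path.
#' @param format `"svg"` or `"png"`.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_zipper <- function(geom, stats = NULL, path, format = c("svg", "png"),
                          width = 6, height = 5) {
  format <- arg_match(format)
  p <- autoplot.zipper_geometry(geom, stats)
  if (format == "svg") {
    grDevices::svg(path, width = width, height = height)
    tryCatch(print(p), finally = grDevices::dev.off())
    # the cairo device numbers raster ids with a session-global counter;
    # renumber them so identical inputs give byte-identical files
    svg_txt <- readr::read_file(path)
    ids <- unique(unlist(stringr::str_extract_all(svg_txt, "source-[0-9]+")))
    for (i in seq_along(ids)) {
      svg_txt <- gsub(ids[i], sprintf("src(%d)", i), svg_txt, fixed = TRUE)
    }
    svg_txt <- gsub("src\\((\\d+)\\)", "source-\\1", svg_txt)
    readr::write_file(svg_txt, path)
    return(invisible(path))
  }
  if (requireNamespace("ragg", quietly = TRUE)) {
    ragg::agg_png(path, width = width, height = height, units = "in", res = 150)
  } else {
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  }
  tryCatch(print(p), finally = grDevices::dev.off())
  invisible(path)
}
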