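#' Summary table of closest peaks
#'
#' One row per feature in input order, listing the closest peak, its width
#' and enrichment; missing hits keep `NA` fields. Per-TSS tissue p-values
#' from [per_tss_tissue_pvalue()] are appended when supplied.
#'
#' @param hits A hit tibble.
#' @param tss_pvals Optional tibble with `label`, `tss_pvalue`.
#' @return A tibble of summary rows.
#' @export
summary_table <- function(hits, tss_pvals = NULL) {
  out <- select(hits, "label", "chrom", "pos", "strand", "sample_id", "assay",
                "peak_start", "peak_end", "distance", "peak_width", "enrichment")
  if (!is.null(tss_pvals)) out <- left_join(out, tss_pvals, by = "label")
  out
}

#' Cross-assay distance matrix
#'
#' For each feature, the best unsigned distance per assay in all-samples
#' mode — the per-TSS view used to compare evidence across assays (CAGE,
#' histone marks, DNase). Missing hits get an `Inf` sentinel.
#'
#' @param features A feature tibble.
#' @param indexes A list of `peak_index` objects, one per assay.
#' @return A tibble: `label` plus one unsigned-distance column per assay.
#' @export
distance_matrix <- function(features, indexes) {
  if (length(indexes) == 0L) {
    abort("distance_matrix() needs at least one assay index",
          class = "zipperplot_config_error")
  }
  cols <- lapply(indexes, function(idx) {
    d <- nearest_across_samples(features, idx)$distance
    ifelse(is.na(d), Inf, abs(d))
  })
  names(cols) <- vapply(indexes, function(idx) idx$assay, character(1))
  bind_cols(tibble(label = features$label), as_tibble(cols))
}

#' @importFrom dplyr bind_cols
NULL

#' Write the distance matrix to TSV
#'
#' @param dm Output of [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  readr::write_tsv(dm, path, progress = FALSE)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

stats_block_html <- function(stats) {
  fmt <- function(v) if (is.null(v) || length(v) == 0 || is.na(v)) "not computed" else fmt_num(v)
  items <- c(ZH = fmt(stats$zh),
             AUZ_global = fmt(stats$auz_global),
             AUZ_left = fmt(stats$auz_left),
             AUZ_right = fmt(stats$auz_right),
             AUZ_window = fmt(stats$auz_window),
             AUZ_window_left = fmt(stats$auz_window_left),
             AUZ_window_right = fmt(stats$auz_window_right),
             window_halfwidth = fmt(stats$window_halfwidth),
             n_features = fmt(stats$n_features),
             n_missing = fmt(stats$n_missing),
             AUZ_pval = fmt(stats$auz_pval),
             AUZ_pval_left = fmt(stats$auz_pval_left),
             AUZ_pval_right = fmt(stats$auz_pval_right),
             permutations = fmt(stats$reps),
             seed = fmt(stats$seed))
  rows <- sprintf("<tr><th>%s</th><td>%s</td></tr>", names(items), items)
  sprintf("<table class='stats'>%s</table>", paste(rows, collapse = ""))
}

table_html <- function(df) {
  if (nrow(df) == 0L) {
    body <- ""
  } else {
    cells <- vapply(seq_len(nrow(df)), function(i) {
      vals <- vapply(df[i, ], function(v) {
        if (is.na(v)) "NA"
        else if (is.numeric(v) && v == round(v)) format(v, scientific = FALSE)
        else if (is.numeric(v)) fmt_num(v)
        else html_escape(as.character(v))
      }, character(1))
      paste0("<tr>", paste0("<td>", vals, "</td>", collapse = ""), "</tr>")
    }, character(1))
    body <- paste(cells, collapse = "\n")
  }
  head <- paste0("<tr>", paste0("<th onclick=\"sortBy(this)\">",
                                html_escape(names(df)), "</th>", collapse = ""), "</tr>")
  sprintf("<table id='summary' class='sortable'><thead>%s</thead><tbody>%s</tbody></table>",
          head, body)
}

sorter_js <- "
function sortBy(th){
  var table = th.closest('table');
  var idx = Array.prototype.indexOf.call(th.parentNode.children, th);
  var tbody = table.tBodies[0];
  var rows = Array.prototype.slice.call(tbody.rows);
  var dir = th.dataset.dir === 'asc' ? -1 : 1;
  th.dataset.dir = dir === 1 ? 'asc' : 'desc';
  rows.sort(function(a, b){
    var x = a.cells[idx].textContent, y = b.cells[idx].textContent;
    var nx = parseFloat(x), ny = parseFloat(y);
    if (!isNaN(nx) && !isNaN(ny)) return dir * (nx - ny);
    return dir * x.localeCompare(y);
  });
  rows.forEach(function(r){ tbody.appendChild(r); });
}"

#' Self-contained HTML report
#'
#' A single static HTML file embedding the zipper plot (base64 PNG or inline
#' SVG), the full statistics block (ZH, all AUZ variants, p-values,
#' permutation count, seed, window) and a sortable summary table. Pure
#' function of its inputs: identical inputs produce identical reports.
#'
#' @param plot_path Path to a rendered plot (`.png` or `.svg`).
#' @param stats A `zipper_stats` object.
#' @param table A summary tibble from [summary_table()].
#' @param out Output HTML path.
#' @param title Report heading.
#' @return `out`, invisibly.
#' @export
html_report <- function(plot_path, stats, table, out, title = "Zipper plot report") {
  if (grepl("\\.svg$", plot_path, ignore.case = TRUE)) {
    img <- paste(readr::read_lines(plot_path), collapse = "\n")
    img <- sub("^<\\?xml[^>]*\\?>", "", img)
  } else {
    b64 <- jsonlite::base64_enc(readBin(plot_path, "raw", file.size(plot_path)))
    img <- sprintf("<img src='data:image/png;base64,%s' alt='zipper plot'/>",
                   gsub("\n", "", b64))
  }
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/><title>",
    html_escape(title), "</title><style>",
    "body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:2px 8px}th{cursor:pointer;background:#eee}",
    "</style><script>", sorter_js, "</script></head><body><h1>",
    html_escape(title), "</h1><h2>Zipper plot</h2>", img,
    "<h2>Statistics</h2>", stats_block_html(stats),
    "<h2>Summary table</h2>", table_html(table),
    "</body></html>")
  writeLines(html, out)
  invisible(out)
}

#' Serialise statistics to a JSON sidecar
#'
#' @param stats A `zipper_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
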