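#' Nearest-rank intron length percentile
#'
#' Pools the intron lengths (gaps between consecutive exons) of all
#' multi-exonic models and returns the q-th percentile by the nearest-rank
#' method: the smallest intron length such that at least q% of introns are
#' at most that long. The 80th percentile over protein-coding genes supplies
#' the default stitching distance.
#'
#' @param genes A model tibble.
#' @param q Percentile in (0, 100].
#' @return Intron length in nt.
#' @export
intron_length_percentile <- function(genes, q = 80) {
  assert_scalar_number(q, "q", min = .Machine$double.xmin, max = 100)
  introns <- unlist(lapply(genes$exons, function(ex) {
    if (nrow(ex) < 2L) return(numeric(0))
    ex$start[-1] - ex$end[-nrow(ex)]
  }))
  if (length(introns) == 0L) {
    abort("no introns: need at least one multi-exonic gene",
          class = "zipperplot_config_error")
  }
  sort(introns)[ceiling(q / 100 * length(introns))]
}

#' Select lncRNAs without nearby CAGE support
#'
#' A lncRNA is CAGE-supported when its best all-samples, strand-matched CAGE
#' peak lies within `radius` nt of its TSS (unsigned distance <= radius,
#' symmetric around the TSS). This returns the unsupported ones: best
#' distance strictly greater than `radius`, or no eligible peak at all.
#'
#' @param lncrnas A model tibble of lncRNAs.
#' @param cage_index A CAGE `peak_index`.
#' @param radius Support radius in nt (default 500).
#' @return The unsupported subset of `lncrnas`, with a `cage_distance`
#'   column (signed; `NA` when no peak exists).
#' @export
select_unsupported <- function(lncrnas, cage_index, radius = 500) {
  if (!identical(cage_index$assay, "CAGE")) {
    abort("select_unsupported() requires a CAGE index", class = "zipperplot_config_error")
  }
  if (nrow(lncrnas) == 0L) return(mutate(lncrnas, cage_distance = double(0)))
  feats <- feature_tibble(label = lncrnas$transcript_id, chrom = lncrnas$chrom,
                          pos = lncrnas$tss, strand = lncrnas$strand)
  d <- nearest_across_samples(feats, cage_index)$distance
  out <- mutate(lncrnas, cage_distance = d)
  out[is.na(d) | abs(d) > radius, ]
}

#' Stitch unsupported lncRNAs to upstream protein-coding genes
#'
#' Emits every (lncRNA, gene) pair on the same chromosome and strand where
#' the gene's 3' end lies upstream of the lncRNA TSS (in transcription
#' direction) within `max_gap` nt. The gap is `tss - end3` on `+` and
#' `end3 - tss` on `-`; 0 (abutting) is allowed, overlap (negative gap) is
#' not, and the bound is inclusive. A lncRNA near several genes yields
#' several candidates.
#'
#' @param unsupported Model tibble of CAGE-unsupported lncRNAs.
#' @param genes Model tibble of protein-coding genes.
#' @param max_gap Maximum stitching distance in nt (default 5827, the 80th
#'   percentile of protein-coding intron lengths).
#' @return A candidate tibble: `lncrna_id`, `lncrna_class`, `gene_id`,
#'   `chrom`, `strand`, `gap`.
#' @export
stitch_candidates <- function(unsupported, genes, max_gap = 5827) {
  assert_scalar_number(max_gap, "max_gap", min = 0)
  pairs <- tidyr::crossing(li = seq_len(nrow(unsupported)), gi = seq_len(nrow(genes)))
  if (nrow(pairs) == 0L) {
    return(tibble(lncrna_id = character(), lncrna_class = character(),
                  gene_id = character(), chrom = character(), strand = character(),
                  gap = double()))
  }
  l <- unsupported[pairs$li, ]
  g <- genes[pairs$gi, ]
  same <- l$chrom == g$chrom & l$strand == g$strand
  gap <- ifelse(l$strand == "+", l$tss - g$end3, g$end3 - l$tss)
  keep <- same & !is.na(gap) & gap >= 0 & gap <= max_gap
  tibble(lncrna_id = l$transcript_id[keep], lncrna_class = l$class[keep],
         gene_id = g$transcript_id[keep], chrom = l$chrom[keep],
         strand = l$strand[keep], gap = gap[keep])
}

overlap_len <- function(a0, a1, b0, b1) pmax(0L, pmin(a1, b1) - pmax(a0, b0))

# max overlap of one interval with a model's exons; also full containment flag
exon_overlap <- function(f0, f1, exons) {
  ov <- overlap_len(f0, f1, exons$start, exons$end)
  list(max = if (length(ov)) max(ov) else 0L,
       full = any(exons$start <= f0 & f1 <= exons$end))
}

# does interval [f0,f1) overlap any exon of any model in `models` by >= k?
overlaps_universe <- function(f0, f1, models, chrom, strand, k) {
  same <- which(models$chrom == chrom & models$strand == strand)
  for (i in same) {
    if (exon_overlap(f0, f1, models$exons[[i]])$max >= k) return(TRUE)
  }
  FALSE
}

#' Score stitch candidates with junction-read evidence
#'
#' A junction supports a candidate when its gene-side flank overlaps an exon
#' of the candidate's gene by at least `min_overlap` nt and its lncRNA-side
#' flank overlaps an exon of the candidate's lncRNA by at least
#' `min_overlap` nt (defaults: at least one junction read, 2 nt on each
#' side). On `+` the gene-side flank is the left (donor) flank; on `-` the
#' flanks swap. Junctions whose flank lies in a region where lncRNA and
#' protein-coding exons overlap cannot be assigned unambiguously and are
#' discarded; the ambiguity test runs against the full lncRNA and
#' protein-coding universes, not just the candidate pair.
#'
#' @param cands Candidate tibble from [stitch_candidates()].
#' @param junctions Junction tibble from [read_junctions_bed12()].
#' @param lncrna_universe Model tibble of all lncRNAs.
#' @param gene_universe Model tibble of all protein-coding genes.
#' @param min_overlap Minimum flank-exon overlap in nt (default 2).
#' @return `cands` with `n_junctions`, `total_junction_reads` and a
#'   list-column `junctions` holding, per candidate, the retained junction
#'   rows with `gene_full`/`lnc_full` containment flags.
#' @export
junction_support <- function(cands, junctions, lncrna_universe, gene_universe,
                             min_overlap = 2) {
  assert_scalar_number(min_overlap, "min_overlap", min = 1)
  empty <- junction_tibble() |> mutate(gene_full = logical(0), lnc_full = logical(0))
  lnc_by_id <- split(lncrna_universe, lncrna_universe$transcript_id)
  gene_by_id <- split(gene_universe, gene_universe$transcript_id)
  details <- lapply(seq_len(nrow(cands)), function(i) {
    cd <- cands[i, ]
    lnc <- lnc_by_id[[cd$lncrna_id]]
    gene <- gene_by_id[[cd$gene_id]]
    jj <- junctions[junctions$chrom == cd$chrom & junctions$strand == cd$strand, ]
    if (nrow(jj) == 0L) return(empty)
    plus <- cd$strand == "+"
    gs <- if (plus) jj$left_start else jj$right_start
    ge <- if (plus) jj$left_end else jj$right_end
    ls <- if (plus) jj$right_start else jj$left_start
    le <- if (plus) jj$right_end else jj$left_end
    keep <- logical(nrow(jj))
    gene_full <- logical(nrow(jj))
    lnc_full <- logical(nrow(jj))
    for (k in seq_len(nrow(jj))) {
      gov <- exon_overlap(gs[k], ge[k], gene$exons[[1]])
      lov <- exon_overlap(ls[k], le[k], lnc$exons[[1]])
      if (gov$max < min_overlap || lov$max < min_overlap) next
      ambiguous <-
        overlaps_universe(gs[k], ge[k], lncrna_universe, cd$chrom, cd$strand, min_overlap) ||
        overlaps_universe(ls[k], le[k], gene_universe, cd$chrom, cd$strand, min_overlap)
      if (ambiguous) next
      keep[k] <- TRUE
      gene_full[k] <- gov$full
      lnc_full[k] <- lov$full
    }
    mutate(jj[keep, ], gene_full = gene_full[keep], lnc_full = lnc_full[keep])
  })
  cands |>
    mutate(junctions = details,
           n_junctions = vapply(details, nrow, integer(1)),
           total_junction_reads = vapply(details, function(d) sum(d$read_count), numeric(1)))
}

#' Bin supported candidates by junction-read totals
#'
#' Counts stitched lncRNAs per biotype class whose junction-read totals fall
#' in the bins `[1, 10]`, `[11, 100]` and `> 100` (candidates with zero
#' supporting reads are excluded). A lncRNA stitched to several genes counts
#' once, through its maximum-support candidate.
#'
#' @param cands Output of [junction_support()].
#' @return A tibble with one row per lncRNA class: `class`, `jr_1_10`,
#'   `jr_11_100`, `jr_gt_100`, `total`.
#' @export
bin_support <- function(cands) {
  classes <- c("mono-exonic", "multi-exonic")
  supported <- filter(cands, .data$total_junction_reads >= 1)
  per_lnc <- if (nrow(supported) == 0L) {
    tibble(lncrna_id = character(), lncrna_class = character(), reads = double())
  } else {
    supported |>
      group_by(.data$lncrna_id, .data$lncrna_class) |>
      summarise(reads = max(.data$total_junction_reads), .groups = "drop")
  }
  counts <- per_lnc |>
    mutate(bin = cut(.data$reads, breaks = c(0, 10, 100, Inf),
                     labels = c("jr_1_10", "jr_11_100", "jr_gt_100"))) |>
    dplyr::count(.data$lncrna_class, .data$bin) |>
    tidyr::pivot_wider(names_from = "bin", values_from = "n", values_fill = 0L)
  out <- tibble(class = classes) |>
    left_join(counts, by = c(class = "lncrna_class"))
  for (col in c("jr_1_10", "jr_11_100", "jr_gt_100")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out |>
    select("class", "jr_1_10", "jr_11_100", "jr_gt_100") |>
    mutate(total = .data$jr_1_10 + .data$jr_11_100 + .data$jr_gt_100)
}

#' Fractions of junction flanks fully inside exons
#'
#' Over all retained junctions (pooled across candidates), the fraction
#' whose gene-side flank lies entirely within a protein-coding exon and the
#' fraction whose lncRNA-side flank lies entirely within a lncRNA exon.
#'
#' @param cands Output of [junction_support()].
#' @return A one-row tibble: `frac_full_gene_overlap`,
#'   `frac_full_lnc_overlap`, `n_junctions`.
#' @export
overlap_fraction_stats <- function(cands) {
  pooled <- bind_rows(cands$junctions)
  if (nrow(pooled) == 0L) {
    abort("no retained junctions to summarise", class = "zipperplot_config_error")
  }
  tibble(frac_full_gene_overlap = mean(pooled$gene_full),
         frac_full_lnc_overlap = mean(pooled$lnc_full),
         n_junctions = nrow(pooled))
}
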