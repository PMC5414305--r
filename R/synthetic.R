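#' Generate a seeded synthetic zipper scenario
#'
#' Emulates the inputs of a real run — a TSS feature set, per-sample peak
#' files, a sample catalog, chromosome sizes and exclusion regions — with
#' every feature's intended nearest peak placed at a controlled signed
#' offset, so downstream query and statistics output can be asserted exactly
#' against the returned truth table. Features are laid out on a spaced grid
#' so that the intended peak is provably the nearest one; decoy samples
#' receive peaks strictly farther by `decoy_extra` nt.
#'
#' The offset rule mirrors the placement regimes of interest: `"point"`
#' places every peak at exactly `offset_value` nt (0 = the closed zipper,
#' every TSS covered by its peak); `"uniform"` draws unsigned offsets
#' uniformly from `offset_range` with random sign. `n_absent` extra features
#' are placed on a dedicated peakless chromosome and so have no hit at all.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_features Per-chromosome feature counts (recycled if scalar).
#' @param assay `"CAGE"` (stranded peaks with tpm) or any ChIP/DNase label.
#' @param n_samples Number of samples; sample `s1` holds the intended peaks.
#' @param offset_kind `"point"` or `"uniform"`.
#' @param offset_value Unsigned offset for `"point"` (0 = overlap).
#' @param offset_range Unsigned offset range for `"uniform"`.
#' @param width_range Peak width range in nt.
#' @param n_absent Features placed on a peakless chromosome.
#' @param decoy_extra Extra distance of decoy-sample peaks beyond the
#'   intended one.
#' @param excl_frac Fraction at the start of each chromosome covered by an
#'   exclusion interval.
#' @param seed Integer seed; all randomness derives from it.
#' @param dir If non-`NULL`, the scenario is also written to files in the
#'   package dialects (`features.tsv`, per-sample peak files, `catalog.tsv`,
#'   `chrom_sizes.tsv`, `exclusions.bed`, `truth.tsv`).
#' @return A list: `features`, `peaks`, `chrom_sizes`, `exclusions`, `truth`
#'   (label, sample_id, signed `distance`, peak coordinates; `NA` for absent
#'   hits), `catalog`, and `paths` when `dir` was given.
#' @export
make_scenario <- function(chrom_sizes = c(chr1 = 1e6, chr2 = 8e5, chr3 = 6e5),
                          n_features = c(40, 30, 30),
                          assay = "CAGE", n_samples = 1,
                          offset_kind = c("uniform", "point"),
                          offset_value = 0, offset_range = c(1, 4999),
                          width_range = c(50, 500), n_absent = 0,
                          decoy_extra = 2000, excl_frac = 0.1, seed = 1,
                          dir = NULL) {
  offset_kind <- arg_match(offset_kind)
  n_features <- rep_len(n_features, length(chrom_sizes))
  max_off <- if (offset_kind == "point") offset_value else max(offset_range)
  spacing <- 2 * (max_off + decoy_extra * (n_samples > 1) + max(width_range)) + 1000
  margin <- spacing
  withr::with_seed(seed, {
    feats <- list(); peaks <- list(); truth <- list()
    for (ci in seq_along(chrom_sizes)) {
      chrom <- names(chrom_sizes)[ci]
      n <- n_features[ci]
      if (n == 0L) next
      if (margin + n * spacing > chrom_sizes[ci]) {
        abort(sprintf("chromosome %s (%g nt) too short for %d features at spacing %g",
                      chrom, chrom_sizes[ci], n, spacing),
              class = "zipperplot_config_error")
      }
      pos <- as.integer(margin + (seq_len(n) - 1L) * spacing +
                          sample.int(200, n, replace = TRUE))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      label <- sprintf("%s_f%d", chrom, seq_len(n))
      feats[[ci]] <- feature_tibble(label, chrom, pos, strand)
      off <- if (offset_kind == "point") rep(offset_value, n) else
        offset_range[1] + sample.int(offset_range[2] - offset_range[1] + 1L, n,
                                     replace = TRUE) - 1L
      genome_side <- sample(c(-1L, 1L), n, replace = TRUE)
      width <- width_range[1] + sample.int(width_range[2] - width_range[1] + 1L, n,
                                           replace = TRUE) - 1L
      t0 <- pos - 1L
      mk_peak <- function(gap, side) {
        start <- ifelse(gap == 0, t0 - (width - 1L) %/% 2L,
                        ifelse(side > 0, t0 + gap, t0 - gap + 1L - width))
        tibble(start = as.integer(start), end = as.integer(start + width))
      }
      intended <- mk_peak(off, genome_side)
      orient <- ifelse(strand == "+", 1L, -1L)
      truth[[ci]] <- tibble(label = label, chrom = chrom, pos = pos, strand = strand,
                            sample_id = "s1",
                            distance = as.numeric(off * ifelse(off == 0, 0L, genome_side) * orient),
                            peak_start = intended$start, peak_end = intended$end)
      per_sample <- lapply(seq_len(n_samples), function(si) {
        pk <- if (si == 1L) intended else mk_peak(off + decoy_extra, genome_side)
        peak_tibble(chrom = chrom, start = pk$start, end = pk$end,
                    strand = if (assay == "CAGE") strand else "*",
                    signal_value = round(runif(n, 1, 20), 3),
                    neglog10_qvalue = if (assay == "CAGE") NA_real_ else
                      round(runif(n, 2, 10), 3),
                    tpm = if (assay == "CAGE") round(runif(n, 0.5, 50), 3) else NA_real_,
                    sample_id = sprintf("s%d", si), assay = assay)
      })
      peaks[[ci]] <- bind_rows(per_sample)
    }
    features <- bind_rows(feats)
    truth <- bind_rows(truth)
    peaks <- bind_rows(peaks)
    if (n_absent > 0) {
      chrom_sizes <- c(chrom_sizes, chrEmpty = 1e5)
      extra_pos <- as.integer(sort(sample.int(9e4, n_absent)) + 1000L)
      extra <- feature_tibble(sprintf("chrEmpty_f%d", seq_len(n_absent)), "chrEmpty",
                              extra_pos, sample(c("+", "-"), n_absent, replace = TRUE))
      features <- bind_rows(features, extra)
      truth <- bind_rows(truth, tibble(label = extra$label, chrom = "chrEmpty",
                                       pos = extra$pos, strand = extra$strand,
                                       sample_id = NA_character_, distance = NA_real_,
                                       peak_start = NA_integer_, peak_end = NA_integer_))
    }
    exclusions <- if (excl_frac > 0) {
      merge_intervals(tibble(chrom = names(chrom_sizes), start = 0L,
                             end = as.integer(floor(chrom_sizes * excl_frac))))
    } else {
      merge_intervals(tibble(chrom = character(), start = integer(), end = integer()))
    }
    out <- list(features = features, peaks = peaks, chrom_sizes = chrom_sizes,
                exclusions = exclusions, truth = truth,
                catalog = tibble(sample_id = sprintf("s%d", seq_len(n_samples)),
                                 assay = assay,
                                 name = sprintf("synthetic sample %d", seq_len(n_samples)),
                                 path = NA_character_))
  })
  if (!is.null(dir)) out <- write_scenario(out, dir)
  out
}

write_scenario <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_features(scn$features, p("features.tsv"))
  readr::write_lines(sprintf("%s\t%d", names(scn$chrom_sizes),
                             as.integer(scn$chrom_sizes)), p("chrom_sizes.tsv"))
  readr::write_lines(sprintf("%s\t%d\t%d", scn$exclusions$chrom,
                             scn$exclusions$start, scn$exclusions$end),
                     p("exclusions.bed"))
  readr::write_tsv(scn$truth, p("truth.tsv"), progress = FALSE)
  assay <- scn$peaks$assay[1]
  paths <- character(0)
  if (identical(assay, "CAGE")) {
    # one CAGE table per sample: intended and decoy intervals differ by sample
    for (s in unique(scn$peaks$sample_id)) {
      f <- p(sprintf("%s_cage.tsv", s))
      write_cage_peaks(scn$peaks[scn$peaks$sample_id == s, ], f)
      paths <- c(paths, f)
    }
    scn$catalog$path <- paths
  } else {
    for (s in unique(scn$peaks$sample_id)) {
      f <- p(sprintf("%s_peaks.narrowPeak", s))
      write_narrowpeak(scn$peaks[scn$peaks$sample_id == s, ], f)
      paths <- c(paths, f)
    }
    scn$catalog$path <- paths
  }
  readr::write_lines(paste(scn$catalog$sample_id, scn$catalog$assay,
                           scn$catalog$name, scn$catalog$path, sep = "\t"),
                     p("catalog.tsv"))
  scn$paths <- list(features = p("features.tsv"), chrom_sizes = p("chrom_sizes.tsv"),
                    exclusions = p("exclusions.bed"), truth = p("truth.tsv"),
                    catalog = p("catalog.tsv"), peaks = paths, dir = dir)
  scn
}

#' Generate a seeded synthetic stitching scenario
#'
#' One (protein-coding gene, lncRNA) pair per chromosome at a controlled gap
#' between the gene's 3' end and the lncRNA TSS, with one junction whose
#' flanks overlap the gene exon and the lncRNA exon by controlled amounts.
#' Ambiguous cases add a second lncRNA whose exon overlaps the gene exon at
#' the junction flank, which must force the junction's exclusion. The truth
#' table states which pairs survive stitching and junction support at the
#' given thresholds.
#'
#' @param pairs A tibble with one row per pair: `gap` (nt), `gene_overlap`
#'   and `lnc_overlap` (nt of junction flank on each exon, 0..8),
#'   `reads` (junction read count), `mono` (logical: mono-exonic lncRNA),
#'   `ambiguous` (logical), `strand` (`+`/`-`).
#' @param max_gap Stitching bound used for the truth table.
#' @param min_overlap Support bound used for the truth table.
#' @param flank_len Junction flank length (nt).
#' @param dir If non-`NULL`, writes `genes.bed`, `lncrnas.bed`,
#'   `junctions.bed`, `chrom_sizes.tsv`, `truth.tsv` there.
#' @return A list: `genes`, `lncrnas`, `junctions`, `chrom_sizes`, `truth`
#'   (with `stitched` and `supported` logicals), and `paths` if written.
#' @export
make_stitch_scenario <- function(pairs = default_stitch_pairs(),
                                 max_gap = 5827, min_overlap = 2,
                                 flank_len = 8, dir = NULL) {
  genes <- list(); lncs <- list(); jxs <- list(); truth <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    chrom <- sprintf("chrS%d", i)
    B <- 10000L
    plus <- pr$strand == "+"
    # gene: two exons (one intron), transcribed toward the lncRNA
    if (plus) {
      gexons <- tibble(start = c(B, B + 300L), end = c(B + 200L, B + 500L))
      gend3_0 <- B + 500L                       # 0-based exclusive end = 1-based end3
      tss1 <- gend3_0 + as.integer(pr$gap)      # gap = tss - end3 (1-based arithmetic)
      lstart <- tss1 - 1L
      lexons <- tibble(start = lstart, end = lstart + 300L)
      if (!pr$mono) lexons <- bind_rows(lexons, tibble(start = lstart + 400L,
                                                       end = lstart + 550L))
    } else {
      lexons <- tibble(start = B, end = B + 300L)
      if (!pr$mono) lexons <- tibble(start = c(B - 250L, B), end = c(B - 100L, B + 300L))
      tss1 <- B + 300L                          # '-' strand: TSS is the largest coordinate
      gstart <- tss1 + as.integer(pr$gap) - 1L  # end3 (1-based) = gstart + 1; gap = end3 - tss
      gexons <- tibble(start = c(gstart, gstart + 300L), end = c(gstart + 200L, gstart + 500L))
    }
    gene <- build_model(sprintf("gene%d", i), sprintf("gene%d", i), "protein_coding",
                        chrom, pr$strand, gexons)
    lnc <- build_model(sprintf("lnc%d", i), sprintf("lnc%d", i), "lncRNA",
                       chrom, pr$strand, lexons)
    genes[[i]] <- gene
    lncs[[i]] <- lnc
    # junction: gene-side flank overlaps a gene exon interior edge by gene_overlap,
    # lncRNA-side flank overlaps the lncRNA exon by lnc_overlap
    feasible <- pr$gene_overlap >= 1 && pr$lnc_overlap >= 1 && pr$reads >= 1
    if (feasible) {
      if (plus) {
        gs0 <- gexons$start[2]                   # anchor at the last exon's start so the
        g0 <- gs0 - (flank_len - pr$gene_overlap)  # flank fits at any gap, incl. gap 0
        g1 <- g0 + flank_len
        ls <- lexons$start[1]
        l1 <- ls + pr$lnc_overlap; l0 <- l1 - flank_len
        jx <- tibble(name = sprintf("jx%d", i), chrom = chrom, strand = pr$strand,
                     read_count = as.numeric(pr$reads),
                     left_start = as.integer(g0), left_end = as.integer(g1),
                     right_start = as.integer(l0), right_end = as.integer(l1))
      } else {
        le <- lexons$end[nrow(lexons)]
        l0 <- le - pr$lnc_overlap; l1 <- l0 + flank_len
        gs <- gexons$start[1]
        g1 <- gs + pr$gene_overlap; g0 <- g1 - flank_len
        jx <- tibble(name = sprintf("jx%d", i), chrom = chrom, strand = pr$strand,
                     read_count = as.numeric(pr$reads),
                     left_start = as.integer(l0), left_end = as.integer(l1),
                     right_start = as.integer(g0), right_end = as.integer(g1))
      }
      feasible <- jx$left_end <= jx$right_start
      if (feasible) {
        jxs[[length(jxs) + 1L]] <- mutate(jx, donor_end = .data$left_end - 1L,
                                          acceptor_start = .data$right_start)
      }
    }
    if (isTRUE(pr$ambiguous)) {
      # decoy lncRNA whose exon covers the gene-side flank region
      amb_exon <- tibble(start = gexons$start[2] - 50L, end = gexons$end[2] + 50L)
      lncs[[length(lncs) + 1L]] <- build_model(sprintf("amb%d", i), sprintf("amb%d", i),
                                               "lncRNA", chrom, pr$strand, amb_exon)
    }
    stitched <- pr$gap >= 0 && pr$gap <= max_gap
    supported <- stitched && feasible &&
      pr$gene_overlap >= min_overlap && pr$lnc_overlap >= min_overlap &&
      !isTRUE(pr$ambiguous)
    truth[[i]] <- tibble(lncrna_id = lnc$transcript_id, gene_id = gene$transcript_id,
                         chrom = chrom, strand = pr$strand, gap = pr$gap,
                         mono = pr$mono, reads = pr$reads,
                         stitched = stitched, supported = supported)
  }
  junctions <- if (length(jxs)) bind_rows(jxs) else junction_tibble()
  out <- list(genes = bind_rows(genes), lncrnas = bind_rows(lncs),
              junctions = junctions,
              chrom_sizes = setNames(rep(50000L, nrow(pairs)),
                                     sprintf("chrS%d", seq_len(nrow(pairs)))),
              truth = bind_rows(truth))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    write_transcript_models_bed12(out$genes, p("genes.bed"))
    write_transcript_models_bed12(out$lncrnas, p("lncrnas.bed"))
    write_junctions_bed12(out$junctions, p("junctions.bed"))
    readr::write_lines(sprintf("%s\t%d", names(out$chrom_sizes), out$chrom_sizes),
                       p("chrom_sizes.tsv"))
    readr::write_tsv(out$truth, p("truth.tsv"), progress = FALSE)
    out$paths <- list(genes = p("genes.bed"), lncrnas = p("lncrnas.bed"),
                      junctions = p("junctions.bed"),
                      chrom_sizes = p("chrom_sizes.tsv"), truth = p("truth.tsv"),
                      dir = dir)
  }
  out
}

#' Boundary-geometry pair set for stitch testing
#'
#' Covers the stitching boundaries (gap 0, the default maximum 5827, one
#' past it), the 1 vs 2 nt junction-overlap boundary on both sides,
#' ambiguous-flank cases, both strands and both lncRNA classes.
#'
#' @return A pairs tibble for [make_stitch_scenario()].
#' @export
default_stitch_pairs <- function() {
  tibble(
    gap = c(0, 2000, 5827, 5828, 2000, 2000, 2000, 2000, 3000, 3000),
    gene_overlap = c(8, 8, 8, 8, 1, 2, 8, 8, 8, 2),
    lnc_overlap = c(8, 8, 8, 8, 8, 2, 1, 2, 8, 8),
    reads = c(5, 50, 200, 10, 3, 3, 3, 0, 12, 7),
    mono = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    ambiguous = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    strand = c("+", "+", "+", "+", "+", "-", "+", "-", "-", "+"))
}
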