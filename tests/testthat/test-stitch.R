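mk_model <- function(id, chrom, strand, exons, biotype = "protein_coding") {
  zipperplot:::build_model(id, id, biotype, chrom, strand,
                           tibble::tibble(start = exons[[1]], end = exons[[2]]))
}

test_that("intron percentile uses the nearest-rank rule", {
  g <- mk_model("g1", "chr1", "+",
                list(c(0, 200, 500, 900, 1400, 2000),
                     c(100, 300, 600, 1000, 1500, 2100)))
  # introns: 100, 200, 300, 400, 500
  expect_equal(intron_length_percentile(g, 80), 400)
  expect_equal(intron_length_percentile(g, 100), 500)
  expect_equal(intron_length_percentile(g, 1), 100)

  # oracle: stats::quantile type 1 is the nearest-rank estimator
  withr::with_seed(111, {
    for (i in 1:20) {
      n_ex <- sample(3:8, 1)
      starts <- cumsum(sample.int(2000, n_ex) + 100)
      gm <- mk_model("g", "chr1", "+", list(starts, starts + 50))
      introns <- starts[-1] - (starts[-n_ex] + 50)
      q <- sample(5:100, 1)
      expect_equal(intron_length_percentile(gm, q),
                   unname(stats::quantile(introns, q / 100, type = 1)))
    }
  })

  same <- mk_model("g2", "chr1", "+", list(c(0, 300, 600), c(100, 400, 700)))
  expect_equal(intron_length_percentile(same, 37), 200)  # all introns equal
  single <- mk_model("g3", "chr1", "+", list(c(0, 500), c(100, 600)))
  expect_equal(intron_length_percentile(single, 80), 400)
  mono <- mk_model("g4", "chr1", "+", list(0, 100))
  expect_error(intron_length_percentile(mono), "no introns")
})

test_that("CAGE support radius is unsigned and strictly bounded at 500", {
  lnc <- dplyr::bind_rows(
    mk_model("near", "chr1", "+", list(10000, 10300), "lncRNA"),
    mk_model("edge_in", "chr1", "+", list(20000, 20300), "lncRNA"),
    mk_model("edge_out", "chr1", "+", list(30000, 30300), "lncRNA"),
    mk_model("nopeak", "chr2", "+", list(1000, 1300), "lncRNA"))
  # tss are 1-based start+1: 10001, 20001, 30001
  peak_at <- function(gap_up) {
    # place peak upstream so that unsigned distance is exactly gap_up
    tibble::tibble(tss0 = c(10000, 20000, 30000), d = c(200, 500, 501))
  }
  pdf <- peak_at()
  pk <- zipperplot:::peak_tibble(chrom = "chr1",
                                 start = as.integer(pdf$tss0 + pdf$d),
                                 end = as.integer(pdf$tss0 + pdf$d + 50),
                                 strand = "+", signal_value = 1,
                                 neglog10_qvalue = NA_real_, tpm = 5,
                                 sample_id = "s1", assay = "CAGE")
  idx <- build_index(pk, c(chr1 = 1e5, chr2 = 1e5))
  un <- select_unsupported(lnc, idx, radius = 500)
  expect_setequal(un$transcript_id, c("edge_out", "nopeak"))
  expect_error(select_unsupported(lnc, build_index(
    dplyr::mutate(pk, assay = "DNase", strand = "*", tpm = NA_real_,
                  neglog10_qvalue = 3), c(chr1 = 1e5)), 500), "CAGE index")
})

test_that("stitching pairs genes strictly upstream within the gap bound", {
  gene <- mk_model("g", "chr1", "+", list(c(5000, 9500), c(6000, 10000)))
  expect_equal(gene$end3, 10000)
  lnc_at <- function(tss1, strand = "+", chrom = "chr1") {
    mk_model(paste0("l", tss1), chrom, strand, list(tss1 - 1, tss1 + 299), "lncRNA")
  }
  cand <- stitch_candidates(lnc_at(12000), gene)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$gap, 2000)

  expect_equal(nrow(stitch_candidates(lnc_at(12000, strand = "-"), gene)), 0L)
  expect_equal(nrow(stitch_candidates(lnc_at(16000), gene)), 0L)        # gap 6000
  expect_equal(stitch_candidates(lnc_at(10000), gene)$gap, 0)           # abutting
  expect_equal(stitch_candidates(lnc_at(15827), gene)$gap, 5827)        # inclusive bound
  expect_equal(nrow(stitch_candidates(lnc_at(15828), gene)), 0L)
  expect_equal(nrow(stitch_candidates(lnc_at(9000), gene)), 0L)         # overlap: no stitch

  # a lncRNA near two genes yields two candidates
  gene2 <- mk_model("g2", "chr1", "+", list(c(7000), c(11000)))
  both <- stitch_candidates(lnc_at(12000), dplyr::bind_rows(gene, gene2))
  expect_equal(sort(both$gene_id), c("g", "g2"))
})

test_that("junction support enforces per-side overlap minima and ambiguity exclusion", {
  scn <- make_stitch_scenario(
    pairs = tibble::tibble(gap = rep(2000, 5),
                           gene_overlap = c(8, 1, 2, 8, 8),
                           lnc_overlap = c(8, 8, 2, 1, 8),
                           reads = c(5, 5, 5, 5, 5),
                           mono = TRUE,
                           ambiguous = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                           strand = "+"))
  un <- scn$lncrnas[grepl("^lnc", scn$lncrnas$transcript_id), ]
  cands <- junction_support(stitch_candidates(un, scn$genes),
                            scn$junctions, scn$lncrnas, scn$genes)
  supported <- cands$lncrna_id[cands$total_junction_reads >= 1]
  expect_setequal(supported, scn$truth$lncrna_id[scn$truth$supported])
  expect_setequal(supported, c("lnc1", "lnc3"))   # 1 nt sides and ambiguous fail

  # monotone: a stricter overlap requirement never retains more junctions
  c2 <- junction_support(stitch_candidates(un, scn$genes),
                         scn$junctions, scn$lncrnas, scn$genes, min_overlap = 3)
  expect_true(all(c2$n_junctions <= cands$n_junctions))
  expect_false("lnc3" %in% c2$lncrna_id[c2$total_junction_reads >= 1])
})

test_that("minus-strand pairs swap the junction flanks correctly", {
  scn <- make_stitch_scenario(
    pairs = tibble::tibble(gap = c(1500, 1500), gene_overlap = c(4, 1),
                           lnc_overlap = c(4, 4), reads = c(9, 9),
                           mono = c(TRUE, FALSE), ambiguous = FALSE, strand = "-"))
  un <- scn$lncrnas[grepl("^lnc", scn$lncrnas$transcript_id), ]
  cands <- junction_support(stitch_candidates(un, scn$genes),
                            scn$junctions, scn$lncrnas, scn$genes)
  expect_equal(cands$lncrna_id[cands$total_junction_reads >= 1], "lnc1")
  expect_equal(cands$total_junction_reads[cands$lncrna_id == "lnc1"], 9)
})

test_that("read-count bins partition candidates at the printed boundaries", {
  mk_cand <- function(id, reads, class = "mono-exonic") {
    tibble::tibble(lncrna_id = id, lncrna_class = class, gene_id = paste0(id, "_g"),
                   chrom = "chr1", strand = "+", gap = 100,
                   junctions = list(tibble::tibble()),
                   n_junctions = 1L, total_junction_reads = reads)
  }
  tab <- bin_support(dplyr::bind_rows(mk_cand("a", 3), mk_cand("b", 50),
                                      mk_cand("c", 200), mk_cand("d", 0)))
  mono <- tab[tab$class == "mono-exonic", ]
  expect_equal(unlist(mono[c("jr_1_10", "jr_11_100", "jr_gt_100", "total")],
                      use.names = FALSE), c(1L, 1L, 1L, 3L))

  bounds <- bin_support(dplyr::bind_rows(mk_cand("w", 10), mk_cand("x", 11),
                                         mk_cand("y", 100), mk_cand("z", 101)))
  mono <- bounds[bounds$class == "mono-exonic", ]
  expect_equal(unlist(mono[c("jr_1_10", "jr_11_100", "jr_gt_100")],
                      use.names = FALSE), c(1L, 2L, 1L))

  zero <- bin_support(mk_cand("a", 0))
  expect_equal(zero$total, c(0L, 0L))

  # each supported candidate lands in exactly one bin; multi-gene lncRNAs count once
  multi <- dplyr::bind_rows(mk_cand("a", 4), mk_cand("a", 40))
  t2 <- bin_support(multi)
  expect_equal(t2$total[t2$class == "mono-exonic"], 1L)
  expect_equal(t2$jr_11_100[t2$class == "mono-exonic"], 1L)  # max-support candidate
  withr::with_seed(121, {
    reads <- sample.int(500, 30)
    t3 <- bin_support(dplyr::bind_rows(lapply(seq_along(reads), function(i)
      mk_cand(paste0("c", i), reads[i]))))
    expect_equal(sum(t3$jr_1_10 + t3$jr_11_100 + t3$jr_gt_100), 30L)
    expect_equal(sum(t3$total), 30L)
  })
})

test_that("full-containment fractions summarise retained junction flanks", {
  scn <- make_stitch_scenario(
    pairs = tibble::tibble(gap = rep(1000, 4),
                           gene_overlap = c(8, 8, 8, 2),
                           lnc_overlap = c(8, 2, 8, 8),
                           reads = 5, mono = TRUE, ambiguous = FALSE, strand = "+"))
  un <- scn$lncrnas
  cands <- junction_support(stitch_candidates(un, scn$genes),
                            scn$junctions, scn$lncrnas, scn$genes)
  fr <- overlap_fraction_stats(cands)
  expect_equal(fr$n_junctions, 4L)
  expect_equal(fr$frac_full_gene_overlap, 0.75)  # the 2 nt gene flank sticks out
  expect_equal(fr$frac_full_lnc_overlap, 0.75)

  none <- junction_support(stitch_candidates(un, scn$genes),
                           zipperplot:::junction_tibble(), scn$lncrnas, scn$genes)
  expect_error(overlap_fraction_stats(none), "no retained junctions")
})

test_that("candidate recovery matches the generated truth across boundary geometries", {
  scn <- make_stitch_scenario()
  un <- scn$lncrnas[grepl("^lnc", scn$lncrnas$transcript_id), ]
  cands <- stitch_candidates(un, scn$genes)
  expect_setequal(cands$lncrna_id, scn$truth$lncrna_id[scn$truth$stitched])
  scored <- junction_support(cands, scn$junctions, scn$lncrnas, scn$genes)
  expect_setequal(scored$lncrna_id[scored$total_junction_reads >= 1],
                  scn$truth$lncrna_id[scn$truth$supported])
  # gap invariants hold on every emitted candidate
  expect_true(all(cands$gap >= 0 & cands$gap <= 5827))
  expect_equal(cands$strand,
               scn$truth$strand[match(cands$lncrna_id, scn$truth$lncrna_id)])
})

test_that("model and junction files round-trip through BED12", {
  scn <- make_stitch_scenario(dir = withr::local_tempdir())
  genes <- read_transcript_models_bed12(scn$paths$genes, "protein_coding")
  expect_equal(genes$transcript_id, scn$genes$transcript_id)
  expect_equal(genes$tss, scn$genes$tss)
  expect_equal(genes$end3, scn$genes$end3)
  expect_equal(genes$exons, scn$genes$exons)
  jx <- read_junctions_bed12(scn$paths$junctions)
  expect_equal(jx[c("chrom", "left_start", "left_end", "right_start", "right_end")],
               scn$junctions[c("chrom", "left_start", "left_end", "right_start", "right_end")])
  expect_equal(jx$read_count, scn$junctions$read_count)
})

test_that("the minimal GTF reader builds the same models as BED12", {
  gtf <- write_tmp(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; biotype "protein_coding";',
    'chr1\tx\texon\t401\t500\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; biotype "protein_coding";',
    'chr1\tx\tCDS\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; biotype "protein_coding";',
    'chr1\tx\texon\t901\t1000\t.\t-\t.\tgene_id "g2"; transcript_id "t2"; gene_biotype "lncRNA";'))
  m <- read_transcript_models_gtf(gtf)
  expect_equal(nrow(m), 2L)
  t1 <- m[m$transcript_id == "t1", ]
  expect_equal(t1$exons[[1]]$start, c(100, 400))   # GTF 1-based inclusive -> 0-based
  expect_equal(t1$exons[[1]]$end, c(200, 500))
  expect_equal(t1$tss, 101)
  expect_equal(t1$end3, 500)
  t2 <- m[m$transcript_id == "t2", ]
  expect_equal(t2$biotype, "lncRNA")
  expect_equal(t2$tss, 1000)
  expect_equal(t2$end3, 901)
})
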