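test_that("narrowPeak fields map to peak columns and bad records are rejected", {
  f <- write_tmp(c("chr1\t100\t250\t.\t0\t.\t6.2\t10.1\t2.0\t75",
                   "chr2\t500\t700\t.\t0\t+\t3.5\t8\t-1\t10"))
  pk <- read_narrowpeak(f, "s1", assay = "DNase")
  expect_equal(pk$chrom, c("chr1", "chr2"))
  expect_equal(pk$start, c(100L, 500L))
  expect_equal(pk$end, c(250L, 700L))
  expect_equal(pk$signal_value, c(6.2, 3.5))
  expect_equal(pk$neglog10_qvalue, c(2.0, NA))  # -1 sentinel -> NA
  expect_true(all(pk$strand == "*"))            # ChIP/DNase stored unstranded
  expect_true(all(is.na(pk$tpm)))

  empty <- write_tmp(character(0))
  expect_equal(nrow(read_narrowpeak(empty, "s1")), 0L)

  degenerate <- write_tmp("chr1\t100\t100\t.\t0\t.\t1\t1\t1\t5")
  expect_warning(pk2 <- read_narrowpeak(degenerate, "s1"), "rejected")
  expect_equal(nrow(pk2), 0L)
})

test_that("broadPeak accepts 9 columns, tolerates extras with a warning, rejects bad starts", {
  ok <- write_tmp("chr1\t10\t90\t.\t0\t.\t4.4\t2\t1.7")
  pk <- read_broadpeak(ok, "s2")
  expect_equal(pk$end, 90L)
  expect_equal(pk$neglog10_qvalue, 1.7)

  extra <- write_tmp("chr1\t10\t90\t.\t0\t.\t4.4\t2\t1.7\t44")
  expect_warning(pk2 <- read_broadpeak(extra, "s2"), "extra trailing columns")
  expect_equal(pk2$signal_value, 4.4)

  neg <- write_tmp("chr1\t-5\t90\t.\t0\t.\t4.4\t2\t1.7")
  expect_warning(pk3 <- read_broadpeak(neg, "s2"), "rejected")
  expect_equal(nrow(pk3), 0L)

  short <- write_tmp("chr1\t10\t90\t.\t0\t.\t4.4\t2")
  expect_error(read_broadpeak(short, "s2"), "line 1")
})

test_that("gappedPeak uses outer coordinates and flags block inconsistencies", {
  two_blocks <- paste("chr3", 1000, 5000, "p", 0, ".", 1000, 5000, "0",
                      2, "100,200", "0,3800", 7.5, 3, 2.2, sep = "\t")
  f <- write_tmp(two_blocks)
  pk <- read_gappedpeak(f, "s1", assay = "ChIP:H3K4me3")
  expect_equal(c(pk$start, pk$end), c(1000L, 5000L))
  expect_equal(pk$signal_value, 7.5)
  expect_equal(pk$neglog10_qvalue, 2.2)
  expect_equal(pk$assay, "ChIP:H3K4me3")

  mismatch <- sub("100,200", "100", two_blocks)
  expect_warning(pk2 <- read_gappedpeak(write_tmp(mismatch), "s1"), "blockSizes")
  expect_equal(nrow(pk2), 1L)

  ninecol <- write_tmp("chr1\t10\t90\t.\t0\t.\t4.4\t2\t1.7")
  expect_error(read_gappedpeak(ninecol, "s1"), "15")
})

test_that("CAGE tables expand to one peak per interval and sample, stranded", {
  f <- write_tmp(c("#chrom\tstart\tend\tname\tscore\tstrand\tliver\tbrain",
                   "chr1\t100\t120\tp1\t0\t+\t3.1\t0.0",
                   "chr2\t500\t540\tp2\t0\t-\t1.5\t9.9"))
  pk <- read_cage_peaks(f)
  expect_equal(nrow(pk), 4L)
  expect_setequal(pk$sample_id, c("liver", "brain"))
  expect_equal(pk$tpm[pk$sample_id == "liver"], c(3.1, 1.5))
  expect_equal(pk$tpm[pk$sample_id == "brain"], c(0.0, 9.9))
  expect_equal(unique(pk$strand[pk$chrom == "chr2"]), "-")
  expect_true(all(pk$assay == "CAGE"))

  nosamples <- write_tmp(c("#chrom\tstart\tend\tname\tscore\tstrand",
                           "chr1\t1\t2\tp\t0\t+"))
  expect_error(read_cage_peaks(nosamples), "no sample columns")

  unstranded <- write_tmp(c("#chrom\tstart\tend\tname\tscore\tstrand\ts1",
                            "chr1\t1\t10\tp\t0\t.\t2.2"))
  expect_error(read_cage_peaks(unstranded), "stranded")

  badtpm <- write_tmp(c("#chrom\tstart\tend\tname\tscore\tstrand\ts1",
                        "chr1\t1\t10\tp\t0\t+\tlots"))
  expect_error(read_cage_peaks(badtpm), "non-numeric tpm")
})

test_that("FDR filter keeps q <= alpha, drops unscored by default, and is monotone", {
  pk <- zipperplot:::peak_tibble(chrom = "chr1", start = c(0, 10, 20, 30),
                                 end = c(5, 15, 25, 35), strand = "*",
                                 signal_value = 1,
                                 neglog10_qvalue = c(2.0, 1.0, 1.4, NA),
                                 tpm = NA_real_, sample_id = "s", assay = "DNase")
  kept <- filter_by_fdr(pk, 0.05)
  # oracle: q = 10^(-col) vs 0.05 directly
  expect_equal(kept$start, pk$start[!is.na(pk$neglog10_qvalue) &
                                      10^(-pk$neglog10_qvalue) <= 0.05])
  expect_equal(kept$start, c(0, 20))
  expect_equal(nrow(filter_by_fdr(pk, 1)), 3L)         # all scored peaks pass
  expect_equal(nrow(filter_by_fdr(pk[0, ], 0.05)), 0L)
  expect_equal(nrow(filter_by_fdr(pk, 0.05, keep_unscored = TRUE)), 3L)

  # idempotent; non-increasing under stricter alpha
  withr::with_seed(11, {
    for (i in 1:20) {
      q <- round(runif(30, 0, 4), 2)
      rpk <- zipperplot:::peak_tibble(chrom = "c", start = seq_along(q) * 10L,
                                      end = seq_along(q) * 10L + 5L, strand = "*",
                                      signal_value = 1, neglog10_qvalue = q,
                                      tpm = NA_real_, sample_id = "s", assay = "DNase")
      alphas <- sort(runif(2, 0.001, 1))
      strict <- filter_by_fdr(rpk, alphas[1])
      loose <- filter_by_fdr(rpk, alphas[2])
      expect_lte(nrow(strict), nrow(loose))
      expect_identical(filter_by_fdr(loose, alphas[2]), loose)
    }
  })
})

test_that("tpm filter is identity by default and strict above the threshold", {
  pk <- zipperplot:::peak_tibble(chrom = "chr1", start = c(0, 10), end = c(5, 15),
                                 strand = "+", signal_value = c(0, 0.2),
                                 neglog10_qvalue = NA_real_, tpm = c(0, 0.2),
                                 sample_id = "s", assay = "CAGE")
  expect_identical(filter_by_tpm(pk, NULL), pk)
  expect_equal(filter_by_tpm(pk, 0)$tpm, 0.2)
  expect_equal(nrow(filter_by_tpm(pk[pk$tpm == 0, ], 0)), 0L)
  chip <- dplyr::mutate(pk, assay = "DNase")
  expect_error(filter_by_tpm(chip, 0), "CAGE")
})

test_that("peak sets round-trip through their source dialects", {
  withr::with_seed(21, {
    np <- random_peaks(25, c(chrA = 1e5), assay = "DNase")
    f1 <- withr::local_tempfile()
    write_narrowpeak(np, f1)
    back <- read_narrowpeak(f1, "s1", assay = "DNase")
    expect_equal(back[c("chrom", "start", "end", "signal_value", "neglog10_qvalue")],
                 np[c("chrom", "start", "end", "signal_value", "neglog10_qvalue")])

    f2 <- withr::local_tempfile()
    write_broadpeak(np, f2)
    back2 <- read_broadpeak(f2, "s1", assay = "DNase")
    expect_equal(back2[c("chrom", "start", "end", "signal_value")],
                 np[c("chrom", "start", "end", "signal_value")])

    base <- random_peaks(10, c(chrA = 1e5), assay = "CAGE")
    # a CAGE table is a complete interval x sample grid of tpm values
    cg <- dplyr::bind_rows(dplyr::mutate(base, sample_id = "s1"),
                           dplyr::mutate(base, sample_id = "s2",
                                         tpm = round(runif(10, 0, 9), 3)))
    cg$signal_value <- cg$tpm
    f3 <- withr::local_tempfile()
    write_cage_peaks(cg, f3)
    back3 <- read_cage_peaks(f3)
    key <- function(x) dplyr::arrange(x[c("chrom", "start", "end", "strand",
                                          "sample_id", "tpm")],
                                      chrom, start, sample_id)
    expect_equal(key(back3), key(cg))
  })
})

test_that("catalog and chromosome-size readers validate their input", {
  sizes <- write_tmp(c("chr1\t1000", "chr2\t2000"))
  cs <- read_chrom_sizes(sizes)
  expect_equal(cs, c(chr1 = 1000L, chr2 = 2000L))

  cat_ok <- write_tmp(c("s1\tDNase\tliver\t/tmp/a.narrowPeak",
                        "s2\tDNase\tbrain\t/tmp/b.narrowPeak"))
  expect_equal(nrow(read_catalog(cat_ok)), 2L)
  cat_dup <- write_tmp(c("s1\tDNase\tliver\t/tmp/a", "s1\tDNase\tliver2\t/tmp/b"))
  expect_error(read_catalog(cat_dup), "duplicate")
})
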