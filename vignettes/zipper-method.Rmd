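---
title: "Validating transcription start sites with zipper plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating transcription start sites with zipper plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipperplot)
```

## The problem

Transcript models reconstructed from RNA-seq — long non-coding RNAs
(lncRNAs) in particular — are often uncertain at their 5′ end: lncRNAs are
lowly expressed, junction-read support is sparse, and single-exon fragments
may be genomic DNA contamination, assembly artefacts, or unannotated
extensions of a neighbouring gene's untranslated region rather than
independent transcriptional units. Independent evidence of transcription
initiation exists in public data: CAGE-seq peaks mark capped 5′ ends,
DNase-seq marks open chromatin, and ChIP-seq peaks for activating histone
marks (H3K4me3, H3K27ac, …) mark active promoters. A putative transcription
start site (TSS) sitting on or near such peaks is far more credible than one
in a peak desert.

zipperplot asks that question for thousands of TSSs at once. The input is
minimal — chromosome, 1-based TSS coordinate, strand, optional label — and
the output is the closest peak per TSS, a ranked "zipper" visualization, and
a small family of statistics with a permutation null.

## Distances and the nearest-peak query

Peaks are BED-convention 0-based half-open intervals `[start, end)`; a TSS
at 1-based position `pos` occupies base `t = pos − 1`. The signed distance
between a TSS and a peak is defined as:

* `0` if and only if `t ∈ [start, end)` — the peak overlaps the TSS. A TSS
  whose converted base equals `end` is outside (half-open convention).
* otherwise the count of bases from the TSS to the nearest peak base:
  `start − t` when the peak is to the right, `t − end + 1` when it is to the
  left. An immediately adjacent peak is at distance 1, never 0, so
  "distance zero" and "overlap" coincide exactly.
* the sign is orientation-aware: positive when the peak lies downstream of
  the feature (greater coordinates for `+` features, smaller for `−`),
  negative when upstream. Flipping a feature's strand negates every nonzero
  distance.

Each (sample, chromosome) peak bucket is sorted by start with a
running-maximum end array, so the nearest peak is found with two
`findInterval()` binary searches even when peaks overlap or nest: the
running maximum locates the left-most covering peak (or the nearest left
edge), and the sorted starts locate the nearest right edge. CAGE peaks are
stranded and only same-strand peaks are eligible; ChIP/DNase peaks are
unstranded. Ties at equal unsigned distance prefer the downstream peak, then
the smaller start; across samples, equal best distances resolve to the
lexicographically smallest sample identifier. These tie rules are arbitrary
but fixed and tested — the alternative (random or input-order ties) would
make runs irreproducible. Every query is verified in the test suite against
a brute-force linear scan written independently from the definition above.

## ZH, AUZ, and the window variant

For a hit set with distances `d₁…dₙ`:

* **Zipper Height** `ZH = #{dᵢ = 0} / n` — the fraction of TSSs overlapped
  by their closest peak. Features with no eligible peak on their chromosome
  stay in the denominator.
* **Area Under the Zipper** `AUZ_global = Σ |dᵢ|` over non-missing hits.
  Each feature contributes a unit-height rectangle reaching from the TSS to
  the nearest peak edge; `AUZ = 0` is the "closed zipper" where every
  closest peak overlaps its TSS, and AUZ grows as the zipper opens, so ZH
  and AUZ are negatively associated by construction. Because peaks need not
  be symmetric around TSSs, `AUZ_left` (upstream hits, `dᵢ < 0`) and
  `AUZ_right` (downstream) are reported separately and always sum to
  `AUZ_global`. The per-feature rectangle realisation is isolated in
  `auz()`; a ranked-curve (trapezoid) alternative could be swapped in behind
  the same interface without touching the rest of the package.
* **`AUZ_window`** clips every `|dᵢ|` at the visualization half-window `w`
  (default 5000 nt), so two zippers drawn with the same window are directly
  comparable. A missing hit behaves like a peak beyond the window and
  contributes `w`, split evenly between the left and right components —
  without this, invisible peaks would make a sparse chromosome look
  well-supported.

## The permutation null

`AUZ` has no useful absolute scale, so significance comes from permutation:
`reps` random TSS sets (default 100) are drawn with the same per-chromosome
feature counts as the input, positions uniform over each chromosome's
allowed bases — the complement of an exclusion set of assembly gaps,
centromeres, telomeres, heterochromatin and repeats, since truly uniform
positions are not plausible TSS locations. Sampling inverts the cumulative
allowed-interval lengths, so it is exact (no rejection loop) and provably
never lands in an excluded base. Strands are copied per chromosome from the
input by default (`preserve_strand`), because CAGE queries are
strand-matched and the strand mix therefore shifts the null; the
alternative (uniform ±) is available since the composition of genuinely
random TSSs is unknowable.

The one-sided p-value is the plain quotient
`#(AUZ_rand ≤ AUZ_observed) / reps` — the chance a random feature set sits
at least as close to peaks as yours. Zero is attainable by design; a
`pseudocount` flag switches to `(k+1)/(reps+1)` for users who need strictly
positive p-values. Sided p-values use `AUZ_left`/`AUZ_right` the same way.
Each replicate's seed is derived as `seed + r`, so runs are reproducible and
the test suite can verify calibration: when the observed features are drawn
from the same blacklisted-uniform generator as the null, the p-value is
uniform (checked at 200 trials × 100 reps within binomial error).

In one-sample mode, a per-TSS tissue p-value is also available: the fraction
of samples with a peak as close or closer than the chosen sample's best
peak, chosen sample included — so its minimum is `1/n_samples` and equal
distances everywhere give 1.

## The plot

`rank_hits()` sorts by unsigned distance (overlaps at rank 1, ties
downstream-first); `build_geometry()` draws each peak from its near edge at
the signed distance, extending by the peak's width away from the TSS and
truncated at ±`w` — peaks whose near edge lies outside the window keep their
rank but draw nothing. `autoplot()` maps rank to the y axis (rank 1 on top),
distance to x with a vertical TSS axis at 0, and `log1p` enrichment (tpm for
CAGE, signalValue otherwise) to a fixed viridis scale; `log1p` because tpm
spans orders of magnitude and is zero-inflated. Rendering is a pure function
of (geometry, stats): the SVG writer renumbers the cairo device's
session-global raster ids so identical inputs give byte-identical files.

## The 5′-boundary audit

If a mono-exonic lncRNA is really the tail of an upstream gene's UTR, its
TSS should lack CAGE support and junction reads should span from the gene's
exons into the lncRNA. The audit implements that argument:

1. **Support filter** — a lncRNA is CAGE-unsupported when its best
   strand-matched, all-samples CAGE distance exceeds 500 nt (unsigned,
   symmetric; the bound is inclusive on the supported side) or no eligible
   peak exists.
2. **Stitching** — each unsupported lncRNA is provisionally joined to every
   protein-coding gene on the same chromosome and strand whose 3′ end lies
   upstream within 5827 nt (inclusive; gap 0 allowed, overlap excluded).
   5827 nt is the 80th percentile of protein-coding intron lengths
   (`intron_length_percentile()`, nearest-rank method), i.e. the joined gap
   is no larger than a common intron.
3. **Junction evidence** — a junction (BED12, TopHat dialect: block sizes
   are flank lengths, score is read count) supports a candidate when its
   gene-side flank overlaps a gene exon and its lncRNA-side flank overlaps a
   lncRNA exon, each by ≥ 2 nt (flanks swap on `−`). Junctions whose flank
   lies where lncRNA and protein-coding exons overlap cannot be assigned and
   are discarded; this ambiguity test runs against the full transcript
   universes, not just the candidate pair, using the same 2 nt threshold.
4. **Summary** — supported candidates are binned by total junction reads
   into `[1,10]`, `[11,100]`, `>100` per lncRNA class; a lncRNA stitched to
   several genes counts once via its maximum-support candidate, since the
   question is per lncRNA, not per pair. `overlap_fraction_stats()` reports
   how often the evidence flanks lie entirely within an exon.

## Synthetic scenarios: what they do and do not show

`make_scenario()` generates every input the pipeline needs from one seed:
features on a spaced grid with intended nearest peaks at controlled signed
offsets (point mass or uniform), decoy samples strictly farther by a fixed
margin, an absent-peak chromosome for missing-hit behaviour, and exclusion
intervals. The grid spacing guarantees the intended peak is provably the
nearest, so the generator's truth table is exact and every downstream number
can be asserted without re-deriving it. `make_stitch_scenario()` does the
same for the audit, one pair per chromosome at controlled gaps, flank
overlaps, read counts and ambiguity geometry, covering the boundary cases
(gap 0 / 5827 / 5828; 1 vs 2 nt overlaps).

The generator emulates formats and geometry, not biology: peak placement is
independent across features, widths and enrichments are uniform draws, and
there is no clustering, no promoter structure, no expression correlation, no
chromosome-scale heterogeneity. Passing tests therefore demonstrate that the
implementation computes its definitions correctly — not that real lncRNA
TSSs will show any particular ZH or AUZ. The defaults (3 chromosomes of
0.6–1 Mb, 100 features, offsets uniform in ±[1, 4999], widths 50–500 nt, 10%
exclusion fraction) keep the suite fast while exercising every code path;
they are scaled-down stand-ins for a genome, chosen once as plausible
magnitudes.

## Parameters, units and defaults

| parameter | default | unit | role |
|---|---|---|---|
| `window_halfwidth` (`w`) | 5000 | nt | plot window and AUZ_window clip |
| `max_features` | 20000 | features | input cap (configurable, not architectural) |
| `reps` | 100 | draws | permutation replicates (1000 for finer p-values) |
| `fdr_alpha` | 0.05 | q-value | ChIP/DNase peak filter, `-log10(q) ≥ -log10(α)` |
| `min_tpm_exclusive` | off | tpm | optional strict CAGE filter (`> 0` etc.) |
| `stitch_radius` | 500 | nt | CAGE support radius in the audit |
| `stitch_max_gap` | 5827 | nt | stitching distance (80th intron percentile) |
| `min_junction_overlap` | 2 | nt | per-side junction flank requirement |

Numerical corner cases are pinned down deliberately: the ENCODE `-1`
q-value sentinel becomes `NA` and such peaks cannot pass the FDR filter
(a `keep_unscored` flag retains them, since a filter on a missing value is a
policy choice, not arithmetic); gappedPeak blocks are discarded because
distances use the outer peak edge; readers accept extra trailing columns
with a warning but reject missing ones; degenerate intervals
(`start ≥ end`) are rejected per record with a warning rather than failing
the file.

## Known limitations

* The distance definition is one coherent reading of "distance to the peak
  edge"; conventions differing by ±1 nt at adjacency exist. All boundary
  behaviour is unit-tested so the convention is at least explicit.
* The permutation null conditions on per-chromosome counts and strand mix
  but not on local context (GC, gene density), so small p-values mean
  "closer than blacklisted-uniform random", nothing stronger.
* Junction input is the BED12 junction dialect; BAM parsing is out of scope
  and junctions must be extracted upstream.
* One consistent genome build is assumed throughout; no coordinate
  conversion is performed.
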