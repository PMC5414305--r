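Package: zipperplot
Title: Zipper Plots for Validating Transcription Start Sites with CAGE, ChIP and DNase Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interrogates putative transcription start sites (TSSs) against
    peak evidence of transcriptional activity. Parses ENCODE
    narrowPeak/broadPeak/gappedPeak and multi-sample CAGE peak tables into a
    binary-searchable per-sample index, retrieves the closest peak to each
    stranded TSS with signed distances, ranks the distances into a zipper
    visualization, and summarises the evidence with the Zipper Height (ZH)
    and Area Under the Zipper (AUZ) statistics, including permutation
    p-values computed against random TSS sets drawn outside blacklisted
    genome regions. Also implements a 5'-boundary audit for long non-coding
    RNAs: lncRNAs lacking nearby CAGE support are provisionally stitched to
    upstream protein-coding genes and scored with splice-junction read
    evidence. Ships a seeded synthetic-scenario generator so the whole
    pipeline is testable without external downloads, plus TSV/JSON/HTML
    reporting and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    ragg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
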