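Package: cutrunr
Title: Downstream Analysis of Antibody-Tethered Nuclease Chromatin Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the downstream analysis of CUT&RUN-style
    antibody-tethered micrococcal nuclease chromatin profiling data:
    reading and size-partitioning mapped paired-end fragment intervals,
    building per-base coverage and fragment-end-density tracks with
    standard or heterologous spike-in normalization, motif-centered
    aggregation (footprint geometry, cleavage periodicity, tram-track
    separation, occupancy scoring and ordering), percentile-threshold
    peak calling, soluble/total chromatin log-ratios, and classification
    of binding sites as direct or indirect via 3D-contact fragment
    pairs. A synthetic-data generator emulates antibody-tethered MNase
    cleavage around transcription-factor sites so that the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
VignetteBuilder: knitr
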