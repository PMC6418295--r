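Package: soykit
Title: Comparative Genomics Toolkit for Wild Soybean Assemblies: Synteny-Based
    Structural Variation, Optical Maps, and RIL Binmap/QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the computational stages used to build
    and exploit a reference-grade wild soybean genome assembly: a built-in
    unique-anchor whole-genome aligner and synteny block utilities,
    insertion and transposable-element insertion calling from adjacent
    alignment-block gaps, large (>100 Kb) inversion and translocation
    detection, assembly evaluation metrics (Nxx, GC and feature tracks,
    telomere and centromeric repeat detection, in silico PCR), optical
    genome map operations (in silico digestion, label merging, molecule
    quality control, repetitive-map filtering, dynamic-programming map
    alignment, region coverage), evidence-classified superscaffold merging
    with head-to-tail gap closing, and recombinant-inbred-line binmap
    construction with LOD-scan QTL mapping and permutation thresholds.
    Synthetic-data generators with planted ground truth make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
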