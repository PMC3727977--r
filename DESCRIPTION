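Package: rmapforge
Title: Optical Map Assembly, Structural Alteration Calling and Copy-Number
    Inference for Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ordered restriction maps ("Rmaps") measured
    from single DNA molecules by Optical Mapping. Provides in-silico digestion
    of genome sequences, a parameterised single-molecule simulator with a
    realistic error model (partial digestion, spurious cuts, sizing noise,
    small-fragment desorption, tumor subclones with distinct copy-number
    profiles), dynamic-programming alignment of Rmaps to a reference
    restriction map, iterative window-based consensus-map assembly including
    hypothesis-driven targeted assembly, classification of consensus-versus-
    reference differences into five classes of optical structural alteration
    (extra cut, missing cut, insertion, deletion, other) with statistical
    support scoring, copy-number segmentation of aligned-molecule coverage
    with a negative-binomial hidden Markov model, per-slice heterogeneity
    analysis, and filtering of somatic candidates against variant panels with
    type-specific intersection windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
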