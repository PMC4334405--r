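Package: hmedip
Title: Tissue-Versus-Culture DNA Modification Profiling from Tiling-Array
    Enrichment Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing 5-methylcytosine (5mC) and
    5-hydroxymethylcytosine (5hmC) immunoprecipitation profiles between a
    primary tissue and cells cultured from it. Provides LOWESS normalization
    of two-channel tiling arrays, running-median smoothing, a percentile-window
    peak caller with permutation-based empirical false discovery rate,
    per-gene differential enrichment testing (Mann-Whitney with
    Benjamini-Hochberg adjustment), signal-degradation diagnostics
    (autocorrelation, Ward clustering, cross-condition correlation), windowed
    read-coverage conventions for enrichment sequencing, a paired
    expression-microarray pipeline, and clone-based bisulfite sequencing
    summarization. A seeded synthetic-data generator plants the expected
    signal structure (global 5hmC attenuation in culture, protected
    imprinted-like loci, clustered promoter 5mC gains, mostly small
    bidirectional expression changes) so every stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    limma,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
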