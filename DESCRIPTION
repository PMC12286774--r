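Package: virseg
Title: Segmented RNA Virus Discovery from Multi-Library Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies complete genome segment sets of segmented RNA viruses
    from multi-library metatranscriptomic assemblies. Contigs carrying the
    RNA-dependent RNA polymerase (RdRP) act as anchors; other contigs whose
    per-library TPM abundance profiles co-occur with an anchor (Spearman
    correlation across libraries) are clustered with it as candidate segments
    of the same virus. Clusters are quality-filtered (cellular-gene,
    single-segment, multi-RdRP, abundance and prevalence rules) and verified
    through conserved terminal sequence motifs, including
    reverse-complementary 5'/3' pairs. Includes a synthetic multi-library
    metatranscriptome generator with ground truth for benchmarking threshold
    choices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'orf.R'
    'abundance.R'
    'config.R'
    'cooccurrence.R'
    'io.R'
    'motifs.R'
    'qc.R'
    'rdrp.R'
    'pipeline.R'
    'simulate.R'
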