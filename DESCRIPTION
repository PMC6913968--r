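Package: MetabarComp
Title: MOTU Filtering, Taxonomic Assignment and Morphology Comparison for
    Macroinvertebrate Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for DNA metabarcoding of freshwater macroinvertebrate bulk
    samples monitored under the EU Water Framework Directive. Implements MOTU
    quality filtering with a cross-contamination threshold derived from an
    artificial internal control, dual-database taxonomic assignment combining
    direct reference hits with a genus-capped lowest-common-ancestor algorithm
    and a rule-based name-resolution engine, redundancy removal against a
    national species register, a six-category concordance analysis of
    morphological versus DNA-based taxon lists, rarefaction, and a synthetic
    community and read-table generator with full ground truth for validating
    the pipeline end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    vegan,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
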