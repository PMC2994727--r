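Package: mesomap
Title: Module-Map Enrichment Analysis of Mesenchymal Signatures in
    Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving median-threshold gene signatures from a
    reference sample, mapping their enrichment across multi-study
    expression compendia with a two-level hypergeometric module map
    (per-sample gene-set calls followed by experiment-set enrichment,
    both under Benjamini-Hochberg false discovery rate control),
    quantifying single-marker prevalence with dual intra-sample and
    cross-sample median thresholds, and clustering expression profiles
    with uncentered Pearson similarity and average linkage. Includes
    readers and writers for GCT, GMT, CLS and plain TSV matrices, the
    compendium normalization strategies used with such data (log2
    transform, joint or per-study gene mean centering), and a seeded
    synthetic-compendium generator with planted gene-set signal for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
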