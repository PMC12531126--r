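Package: clonetrace
Title: Tracing Metastatic Spread from Multiregional Copy-Number and
    Targeted-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the spatiotemporal spread of tumor subclones in
    multiregionally sampled solid tumors. Converts per-segment SNP-array
    measurements (log2 ratio, mirrored B-allele frequency, allelic
    composition) into mutated sample and clone fractions, estimates sample
    purity, applies a multi-caller consensus filter to targeted-sequencing
    variant calls, deconvolves subclones from clone-fraction profiles
    across samples, reconstructs rooted maximum-parsimony clone trees from
    binary event matrices, and classifies each patient's metastatic
    pattern (earlier/later seeding, monoclonal/polyclonal,
    monophyletic/polyphyletic, intermetastatic spread) together with a
    per-site index of genomic diversity. Includes a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    phangorn
Config/testthat/edition: 3
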