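Package: panretain
Title: Population-Based Comparative Gene Retention Analysis Across Pangenome Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative gene retention analysis across pangenome
    panels of species with differing ploidy. Computes per-orthogroup gene
    retention rates from presence/absence matrices, filters for monotone
    dosage-constraint retention patterns, classifies gene duplicates
    (tandem, proximal, dispersed, WGD/segmental) from homology hits and
    collinear blocks, estimates pairwise Ka/Ks by Nei-Gojobori counting,
    fits codon substitution models (one/two/n-ratio branch models and
    branch-site Model A) with likelihood-ratio tests, and performs
    hypergeometric GO over-representation tests. Includes seeded synthetic
    pangenome, genome-layout, codon-evolution, and annotation generators
    with ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
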