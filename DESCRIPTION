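Package: g4scan
Title: RNA G-Quadruplex Detection, Subtype Classification and Variant Effect Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for RNA G-quadruplex (rG4) analysis:
    rule-based detection and hierarchical subtype classification of rG4
    motifs, reference window scorers (G4Hunter, cGcC), a miniature
    transformer masked language model over overlapping 6-mer tokens with
    binary and multiclass fine-tuning heads, delta-score scanning of
    single-nucleotide variants, integrated-gradients attribution and
    flank perturbation maps, position-weight-matrix enrichment statistics
    for rG4 flanking regions, and a population-genetics comparison suite
    for rG4-altering variants. Ships seeded synthetic-data generators with
    known ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
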