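Package: layerid
Title: Multilayered Protein Identification for Genome-Unsequenced Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A layered MALDI-TOF/TOF protein identification pipeline for
    organisms without a sequenced genome. Layer 1 performs a combined peptide
    mass fingerprint and MS/MS probability-scored search against a protein
    database; layer 2 searches six-frame translations of an EST database and
    annotates matched ESTs by gapped local alignment with Karlin-Altschul
    significance; layer 3 infers peptide sequences de novo from spectrum
    graphs and submits the reliable candidates to a gapless, mass-ambiguity
    tolerant homology search over merged query strings. Includes a synthetic
    MALDI spot generator with known ground truth, in-silico tryptic
    digestion, theoretical fragment-ion models, MGF input/output, and
    per-spot confidence reporting with taxonomic and functional summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
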