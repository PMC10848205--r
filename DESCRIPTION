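Package: biopanr
Title: Biopanning Display-Library Sequence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for bacterial surface-display biopanning
    experiments sequenced as amplicon reads. Extracts anchor-bounded
    display-peptide inserts from FASTQ reads, translates and classifies
    them (valid, stop codon, frame shift, blank, unknown residue),
    computes round-level amino-acid composition analytics (normalized
    frequencies, chemical-class aggregation, positional counts, length
    distributions, round-over-round deltas), motif-level statistics
    (k-mer fragments, pairwise residue co-occurrence, top-N sequence
    ranking and cross-set overlap), and magnetophoretic
    separation-efficiency statistics from colony-count tables. Includes
    a seeded synthetic amplicon-read generator with per-read ground
    truth so every pipeline stage can be validated against known
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
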