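Package: teepi
Title: Transposable-Element Epigenetic Effect Inference from Multi-Strain
    ChIP and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects epigenetic effects of polymorphic transposable element
    (TE) insertions by comparing histone-mark fold-enrichment (H3K9me3,
    H3K27ac) between genomes carrying and lacking each insertion. Projects
    insertion breakpoints into TE-free genomes from flank alignments, builds
    1 kb window profiles of binned ChIP signal around each insertion, calls
    per-TE enrichment or depletion with a percentage magnitude and a spread
    extent via consecutive per-window rank-sum tests, and applies a consensus
    rule across strain pairs. Links affected TEs to nearby genes through
    TMM-normalized expression z-scores, provides permutation null models
    against positionally matched TE sets and TE-free control regions, and
    family-level proportion tests. Includes a synthetic multi-strain cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
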