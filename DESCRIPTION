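Package: quadmeth
Title: Strand-Resolved CpG Methylation Analysis Around G-Quadruplex Motifs
Version: 0.1.0
Authors@R: person("quadmeth", "developers", role = c("aut", "cre"),
    email = "quadmeth@example.org")
Description: Analysis of in vitro CpG-island methylation experiments read out
    by single-molecule sequencing with per-read modification probabilities.
    Provides G4Hunter-style scoring and interval calling of potential
    G-quadruplex-forming sequences (PQS) on an amplicon, strand-resolved
    confidence-thresholded methylation pileups from per-read (C, 5mC, 5hmC)
    probability calls, a modification-calling accuracy statistic, region by
    strand differential-methylation summaries with Welch t-tests, 1:1
    biolayer-interferometry kinetic fits, log-logistic IC50 inhibition fits,
    and a restriction-protection methylation-efficiency calculation.
    Synthetic-data generators emulate the sequencing and instrument inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    Biostrings,
    Rsamtools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
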