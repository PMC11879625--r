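Package: isledv
Title: Island Size and Genome-Wide Diversity from Single-Individual Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline linking island area to genomic diversity when one
    diploid individual is sequenced per island. Computes invariant-aware
    observed heterozygosity from all-sites VCFs, calls runs of homozygosity
    with a fixed-width window rule, counts homozygous non-reference
    endogenous retrovirus (ERV) insertions from MELT-style polymorphism
    calls, converts scaled MSMC2 output into real-time effective population
    size trajectories with recent and harmonic-mean summaries, and fits the
    island-size statistical layer (log-area regressions, correlograms, and
    LASSO variable selection). A synthetic-archipelago generator with known
    ground truth exercises and validates every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    glmnet,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
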