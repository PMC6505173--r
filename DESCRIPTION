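Package: doqc
Title: Quality Control Diagnostics for Diversity Outbred Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnostics and cleaning tools for SNP array genotypes from
    Diversity Outbred (DO) mice and similar eight-founder multiparent
    populations.  Provides sample-level checks (missing data, sex
    verification from X/Y probe intensities, duplicate detection, array
    intensity profiles, genotype frequencies by founder minor allele
    frequency, crossover counts, genotyping-error rates), marker-level
    checks, a 36-state diplotype hidden Markov model with genotyping-error
    LOD scores, the Carter-Falconer map function, and a seedable simulator
    of DO-like datasets with known truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
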