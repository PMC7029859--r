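Package: sdsim
Title: Simulation and Detection of Segregation Distortion in Biparental
    Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates genotyping data for single-seed-descent (RIL)
    populations derived from a biparental cross, with locus-specific
    gametic viability selection, and provides the statistical machinery
    to detect segregation distortion: per-marker chi-square
    goodness-of-fit tests against Mendelian ratios (1:2:1 in F2, 1:1
    homozygotes in advanced generations), the magnitude-of-distortion
    statistic M = a/(a+b), Benjamini-Hochberg and Bonferroni multiple
    testing corrections, segregation distortion region (SDR) detection,
    and linkage diagnostics (crossover counts, recombination-proxy
    distances, map-length estimates).  A Monte-Carlo experiment harness
    measures type-I error, familywise null rates and power of the
    different detection criteria across population sizes, filial
    generations and selection strengths.  Simulated populations can be
    exported in MSTMap format for genetic map construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
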