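Package: msatpower
Title: Sample-Size Effects on Microsatellite Diversity and Population
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how sample size biases within-population
    genetic-diversity metrics and the power to detect population
    differentiation in diploid microsatellite data. Provides Genepop
    reading and writing, per-population diversity summaries (allele
    counts, rarefied allelic richness, effective alleles,
    heterozygosities, FIS), Weir-Cockerham theta and Hedrick's G'ST with
    bootstrap confidence intervals, Monte-Carlo exact genic tests
    combined across loci by Fisher's method, a forward-time bottleneck
    simulator with overlapping generations, drift-only and finite-island
    divergence simulators, a rarefaction/subsampling pipeline, and power
    grids over sample size, effective population size and migration
    rate, plus a synthetic-data generator emulating an empirical limpet
    microsatellite panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
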