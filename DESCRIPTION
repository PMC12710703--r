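Package: popgenerode
Title: Temporal Population Genomics of Bottleneck-Driven Genomic Erosion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying genomic erosion between historical and
    contemporary cohorts of a wild population that passed through a recent,
    human-induced bottleneck. Includes an individual-based forward
    Wright-Fisher simulator with a deleterious distribution of fitness
    effects that doubles as a synthetic-data generator; genotype filters for
    merged low-coverage historical/contemporary variant data (allele-balance
    recoding and a deamination-guard transition filter); genome-wide
    heterozygosity and hidden-Markov-model runs-of-homozygosity estimation
    (F_ROH); potential and realized mutation-load summaries with the R_x/y
    statistic and chromosome-jackknife confidence intervals; and utilities
    for effective-population-size trajectories (census-size conversion,
    generation-time calibration, the G robustness statistic, and
    catch-record correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
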