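Package: lofkit
Title: Loss-of-Function Constraint, Cumulative Allele Frequency and Human
    Knockout Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic toolkit for predicted loss-of-function (pLoF) variation
    in human population cohorts. Estimates per-gene cumulative pLoF allele
    frequency from carrier fractions under a conservative cis assumption,
    models heterozygote and two-hit ("human knockout") genotype frequencies
    under outbred, bottlenecked and consanguineous population structure,
    projects the sample sizes needed to discover two-hit individuals or infer
    lethality from their absence, computes region-restricted pLoF constraint
    with exact Poisson upper bounds, classifies genes into a knockout
    discovery roadmap, compares constraint between gene sets, and performs
    genetic prevalence arithmetic. A bundled synthetic-cohort simulator
    generates gene catalogs and cohort genotypes with the statistical
    structure the closed forms assume, so the whole pipeline is testable
    without external call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
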