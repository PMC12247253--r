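Package: colonykin
Title: Pedigree Kinship and Inbreeding-Depression Analysis for Closed Breeding Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing multi-decade breeding records of closed
    captive colonies. Builds a pedigree from litter records, computes dam-sire
    kinship by the classical recursion with ancestor tracing truncated at a
    configurable generation depth, and quantifies inbreeding depression in
    pre-weaning pup loss with weighted binomial-logit models (McFadden pseudo
    R-squared, likelihood-ratio tests), Pearson correlations, relatedness
    binning with one-way ANOVA, cumulative-by-year trend scans with breeding
    phase annotation, sex-specific loss imputation under a 1:1 birth sex
    ratio, and litter-interval analysis. A discrete-event colony simulator
    with relatedness-dependent pup mortality and delivery intervals provides
    ground truth for parameter-recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
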