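Package: metgs
Title: Training Set Optimization for Genomic Selection in Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Design of phenotyping training sets for genomic selection across
    multiple environments. Implements the marker-by-environment mixed model
    with a compound-symmetry genetic covariance across environments, genomic
    BLUP of candidate genotypic values and its prediction covariance, the
    CDmean(v2) and CDmean.MET generalized coefficient-of-determination design
    criteria, a genetic-algorithm subset optimizer with a random-sampling
    baseline, restricted maximum likelihood estimation of the variance
    components, and a simulation engine that scores designs with ranking
    metrics (NDCG, rank correlation and rank-sum ratio at top-k) for
    identifying superior genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
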