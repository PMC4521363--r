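Package: skellamAEI
Title: Folded Skellam Mixture Models for Allelic RNA Expression Imbalance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects allelic RNA expression imbalance (AEI) at heterozygous
    SNPs from RNA-seq allele read counts. SNPs are first grouped into
    comparable coverage classes with a finite Poisson mixture fitted by EM
    with BIC model selection; within each class, AEI is detected by fitting a
    mixture of folded Skellam distributions to the absolute library-adjusted
    allelic read differences and testing each component for unequal Poisson
    rates with a likelihood-ratio test. Includes exact Skellam and folded
    Skellam probability functions, an approximate-Bayesian-computation MCMC
    fitting backend, a synthetic allele-count generator with a shared latent
    coverage component, and an end-to-end pipeline with cross-region
    consistency reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
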