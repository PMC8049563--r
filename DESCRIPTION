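Package: twotwo
Title: Population Divergence Times from Two-Individual Sample Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form coalescent estimators of population divergence time,
    branch-specific genetic drift, and ancestral effective population size from
    the joint site-frequency spectrum of two diploid individuals, one sampled
    from each of two populations (the "TT" method), together with an
    outgroup-ascertained variant ("TTo") that relaxes the constant
    ancestral-population-size assumption and provides tree-ness tests of the
    outgroup topology. Includes a per-site coalescent simulator for
    two-population split demographies with piecewise-constant ancestral size
    and a single pulse of admixture, site-table tallying with ancestral-allele
    polarization and outgroup ascertainment, and weighted block-jackknife
    standard errors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
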