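Package: clonepart
Title: Partitioning Additive and Non-Additive Genetic Variance in
    Clonally Replicated Full-Sib Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning the total genetic variance of clonally
    replicated full-sib tree families into additive and non-additive
    components using genomic relationships. Provides a simulator for
    clonal field trials (linkage-map based gamete sampling, randomized
    complete blocks, separable AR1-by-AR1 spatial residuals), within-family
    genotype quality control including Mendelian-inconsistency screening
    and detection of hidden half-sib paternity mixtures, VanRaden method-1
    genomic relationship matrices with family-internal allele frequencies,
    a REML engine for spatial mixed models that combine genotyped and
    ungenotyped clones under the constraint that the total genetic variance
    equals k times the additive variance plus the non-additive variance,
    and profile-likelihood inference with pooling across families and sites
    for the additive fraction of genetic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
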