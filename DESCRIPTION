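Package: radpop
Title: Demographic Inference and Standing Variation Analysis for Two-Ecotype
    RAD-seq Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying parallel ecotype divergence with multi-locus
    SNP and haplotype data. Provides a two-deme structured-coalescent
    simulator with heterogeneous gene flow (genomic islands) and linked
    selection (local effective-size reduction), construction, projection and
    folding of joint allele frequency spectra, Poisson composite-likelihood
    fitting and AIC comparison of strict-isolation, isolation-with-migration
    and secondary-contact models, conversion of mutation-scaled estimates to
    biological units, per-locus diversity and divergence statistics
    (nucleotide diversity, d_XY, Tajima's D, haplotype and Weir-Cockerham
    F_ST, LD decay, Mantel tests, empirical outlier scans), SNP retention
    filters, and resampling accumulation curves quantifying standing genetic
    variation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'constructors.R'
    'simdata.R'
    'demography.R'
    'filters.R'
    'io.R'
    'standvar.R'
    'popstats.R'
    'unitconv.R'
    'spectra.R'
    'pipeline.R'
    'radpop-package.R'
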