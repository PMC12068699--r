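Package: aiqtl
Title: Allelic-Imbalance QTL Detection with Symmetric Beta-Binomial Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether the genotype of a candidate regulatory variant is
    associated with the extent of allelic imbalance of a gene (an
    allelic-imbalance QTL, or aiQTL). Per-sample allele-specific read counts
    are modelled with a two-component mixture of symmetric beta-binomial
    distributions whose mixing weight may depend on whether a sample is
    heterozygous or homozygous at the variant; nested models are compared by
    likelihood ratio. Includes per-sample imbalance estimation, comparator
    tests (binomial, proportion-threshold, Wilcoxon, independent
    beta-binomial fits), simulation designs for calibration and power
    studies, dataset-level scanning with distance-to-TSS logistic modelling,
    downsampling analysis, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
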