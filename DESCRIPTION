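Package: sphmm
Title: Polygenic Architecture Estimation from GWAS Summary Statistics via
    Semi-Parametric Hierarchical Mixture Models
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Empirical Bayes estimation of the polygenic architecture of
    complex diseases from genome-wide association study (GWAS) summary
    statistics. A two-group semi-parametric hierarchical mixture model
    decomposes per-SNP log-odds-ratio estimates into a null component and a
    non-null component whose effect sizes follow a nonparametric prior
    supported on a fixed grid. A three-stage smoothing-and-roughening EM
    schedule estimates the proportion of disease-associated SNPs and the
    effect-size distribution; parametric bootstrap provides standard errors.
    Utilities convert fitted log-odds ratios to liability-scale explained
    variance under the liability threshold model, compute per-SNP posterior
    effect sizes, perform P-value-based and random LD pruning, derived
    allele frequency binning, stratified fits, and simulate case-control
    summary statistics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
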