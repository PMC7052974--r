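Package: poolscreen
Title: Simulation and Asymmetry-Aware Analysis of Pooled CRISPR Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of pooled CRISPR knockout screens
    (lognormal plasmid library, viral transduction, bottlenecked
    proliferation with exponential growth and cell-splitting subsampling,
    PCR/sequencing) together with a statistical test for gene essentiality
    that models the asymmetric null distribution of guide-level log fold
    changes: a stratified skew-normal null fitted by trimmed
    quantile-matching (least quantile of squares), guide-level p-values,
    and alpha-cutoff robust rank aggregation to the gene level with
    permutation p-values. Includes ground-truth benchmarking
    (precision-recall, recall at fixed precision) and coverage
    recommendation for experiment design.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
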