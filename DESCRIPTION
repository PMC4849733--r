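Package: medianMR
Title: Median-Based Robust Causal Estimation for Summary-Data Mendelian
    Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust causal-effect estimation from per-variant GWAS summary
    statistics. Implements the simple, weighted and heterogeneity-penalized
    weighted median estimators together with the inverse-variance weighted
    (IVW) and MR-Egger regression comparators, parametric-bootstrap standard
    errors and confidence intervals for the median-based methods, genome-wide
    variant selection rules, scatter and funnel diagnostics, and a simulation
    engine covering balanced, directional and confounder-mediated pleiotropy
    in one- and two-sample designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
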