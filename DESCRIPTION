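Package: avflux
Title: Arteriovenous Metabolomics of Interorgan Metabolite Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of arteriovenous (AV) metabolomics
    experiments in which blood is sampled upstream and downstream of
    individual organs. Computes per-animal log2 venous/arterial abundance
    ratios with organ-specific arterial references (including weighted
    inflow mixtures such as the hepatic artery / portal vein supply of the
    liver), classifies metabolite release and uptake per organ with
    normality-gated one-sample tests and Benjamini-Hochberg FDR, builds
    interorgan source-to-sink exchange graphs, screens for homeostatic
    (concentration versus flux) coupling with Spearman correlation, and
    derives creatinine-normalized renal reabsorption and stable-isotope
    tracer leakage indices. Includes LC-MS preprocessing (internal-standard
    normalization, injection-replicate collapsing, pooled-QC CV filtering)
    and a synthetic littermate-paired cohort generator with known ground
    truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
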