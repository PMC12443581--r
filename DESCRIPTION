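Package: meriparray
Title: Analysis of m6A Epitranscriptomic Two-Channel Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for MeRIP (methylated-RNA immunoprecipitation)
    two-channel microarray experiments that hybridize Cy5-labelled IP
    RNA against Cy3-labelled supernatant RNA on the same slide.
    Implements spike-in log2 normalization, the per-transcript
    m6A-quantity and gene-expression-level statistics, two-group
    differential methylation and expression calling with
    Benjamini-Hochberg correction, sample-level hierarchical
    clustering, joint methylation-by-expression quadrant
    classification and global association, Fisher's-exact-test
    over-representation analysis against user-supplied gene sets, and
    MeRIP-qPCR percent-input and 2^-ddCt calculators. A synthetic-data
    generator with planted differential methylation and expression
    supports calibration and power studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
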