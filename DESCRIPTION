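Package: coorient
Title: Co-Orientational Order of Paired Axial Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the correlation and consistency of orientation between
    two co-localized fields of axial (period-pi) data, such as cytoskeletal
    constructs extracted from fluorescence micrographs. Implements the
    orientational order parameter (OOP) via the 2x2 nematic order tensor, the
    co-orientational order parameter (COOP) of the relative-angle field, its
    analytic uncorrelated and correlated bounds, a normalized COOP with
    regime classification, error propagation with t-test based maximum
    tolerable error and minimum sample size surfaces, seeded synthetic
    orientation-field generators for validation, and a grid-based weighted
    pipeline for image-scale angle fields including pairwise consistency
    matrices and multi-sample mean-angle statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
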