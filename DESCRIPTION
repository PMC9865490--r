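Package: stromatalk
Title: Tumor-Stroma Deconvolution and Ligand-Receptor Crosstalk Scoring
    for Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tumor purity from bulk RNA-seq expression via
    rank-based stromal/immune signature scoring, deconvolves each cohort's
    expression into nonnegative tumor and stroma compartment means by
    non-negative least squares on the purity-weighted two-compartment
    mixture model, and scores every ligand-receptor pair's four directional
    interactions (tumor-to-tumor, tumor-to-stroma, stroma-to-tumor,
    stroma-to-stroma) with a mass-action relative crosstalk statistic.
    Includes percentile-bootstrap confidence intervals for compartment
    means, per-direction rankings of top pairs, a synthetic-cohort
    generator with known ground truth for end-to-end verification, and an
    end-to-end pipeline driver with TSV/JSON/figure outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
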