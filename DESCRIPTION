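Package: mxifhet
Title: Single-Cell Heterogeneity Analysis of Multiplexed Immunofluorescence Breast Cancer Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative single-cell analysis of multiplexed immunofluorescence
    (MxIF) tissue microarray data from breast cancer. Provides per-marker
    min-max normalization to the 0-15 scale, IHC-calibrated marker
    thresholding, eight-group ER/PR/HER2 (EPH) co-expression classification
    crossed with Ki67 into sixteen single-cell classes, St. Gallen
    IHC-surrogate subtyping of cores, cancer-cell gating by size,
    pan-cytokeratin level and region annotations, radius-based spatial
    neighborhood composition with Shannon equitability diversity, immune
    (CD8/CD20) density and neighborhood profiling, paired-core intra-tumoral
    heterogeneity testing (Wilcoxon plus permutation), and a synthetic tissue
    microarray generator with recorded ground truth for validation.
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
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
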