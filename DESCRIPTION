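Package: mifspatial
Title: Phenotyping, Reproducibility and Spatial Pattern Analysis for
    Multiplex Immunofluorescence Cell Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of per-cell tables exported from multiplex
    immunofluorescence (mIF) image analysis: coordinate-based merging of
    per-marker segmentation tables, marker co-expression phenotyping against
    five immuno-oncology panels, cell density (cells/mm^2) and
    percent-of-DAPI quantification per region of interest, two-timepoint
    reproducibility statistics (coefficient of variation, within- and
    across-sample Spearman correlation with Bonferroni adjustment),
    nearest-neighbour proximity analysis between malignant-cell and immune
    phenotypes, and classification of tumours into mixed or unmixed spatial
    patterns by comparing the empirical cross-type nearest-neighbour G
    function with its theoretical Poisson counterpart. A synthetic tissue
    generator produces marked point patterns with clustered malignant nests,
    tunable immune infiltration and noisy two-timepoint replicates so the
    whole pipeline can be exercised without access to patient data.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
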