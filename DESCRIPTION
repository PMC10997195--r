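Package: omiHet
Title: Optical Metabolic Imaging Heterogeneity and Metabolomics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for longitudinal in vivo optical
    metabolic imaging of tumor xenografts. Provides dark-noise and
    pre-injection background correction with Rhodamine B session
    calibration, pooled pixel-intensity distributions compared by
    Kolmogorov-Smirnov tests under mouse-blocked permutation nulls,
    pixel-wise 2x2 metabolic clustering of glucose-uptake (2-NBDG) and
    mitochondrial-membrane-potential (TMRE) images with area-fraction
    heterogeneity readouts, caliper-based tumor trajectory staging, and a
    targeted-metabolomics stage (sum normalization, log transform, Pareto
    scaling, volcano classification, batch centering). A synthetic-cohort
    generator with recorded ground truth makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tiff,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
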