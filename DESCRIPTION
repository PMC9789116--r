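Package: ruvtax
Title: Removing Unwanted Variation from Microbiome Taxon Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates and removes unknown unwanted technical variation
    (sequencing depth, storage, freeze-thaw, library kit effects) from
    taxon-by-sample count matrices using a negative binomial log-linear
    factor model informed by technical replicates and negative-control
    taxa. Provides percentile-invariant adjusted counts, identification
    of empirical negative-control taxa, RLE- and silhouette-based
    evaluation of correction quality, Storey pi0 estimation, pseudo-R2
    attribution of unwanted factors to individual taxa, factor-analytic
    RUVg/RUVs baselines, and a synthetic count generator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
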