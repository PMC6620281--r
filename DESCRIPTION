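Package: lsnquant
Title: Liver Surface Nodularity Quantification from Abdominal MR Slices
Version: 0.1.0
Authors@R:
    person("LSN", "Maintainers", email = "lsnquant@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of liver surface nodularity (LSN)
    from 2-D abdominal MR slices. Implements multiplicative bias-field
    correction and liver segmentation by a local-intensity-clustering level-set
    energy, sub-pixel liver surface line extraction with arc-length
    resampling, polynomial curve fitting of surface regions of interest, and
    the residual-based LSN score. Includes a seedable synthetic liver phantom
    generator with known boundary nodularity for validation, and a diagnostic
    statistics layer (Kruskal-Wallis, Mann-Whitney, Wilcoxon signed-rank,
    coefficient of variation, ICC(2,1), ROC/AUC with DeLong intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
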