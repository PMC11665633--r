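Package: ldamarker
Title: Biomarker Discovery by Linear Discriminant Analysis Effect Size
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential-abundance biomarker discovery for two-class
    microbiome and metagenomic feature tables using the LDA effect size
    (LEfSe) approach: a Kruskal-Wallis screen across classes, a strict
    sign-consistent Wilcoxon rank-sum screen across subclass strata, and a
    direct (seed-free, noise-free) full-data linear discriminant analysis
    yielding signed log10 effect-size scores. Includes barplot, per-feature
    abundance histogram, and taxonomic cladogram visualizations with a
    color-blind-safe default palette, a compositional synthetic-data
    generator with spike-in ground truth, a bootstrap-averaging reference
    estimator, and stability/ranking benchmark experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
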