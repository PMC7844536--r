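Package: wolbaq
Title: Quantification and Statistics for Intracellular Wolbachia Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying the relative density of intracellular
    Wolbachia from multi-channel confocal z-stacks and for the downstream
    statistical analyses used in endosymbiont density studies: a
    cell-type-of-interest versus surrounding-cells voxel-density ratio with
    slice selection rules, a normality-gated group-comparison decision tree
    (Mann-Whitney U or Welch t, Kruskal-Wallis with Dunn-Bonferroni or ANOVA
    with Tukey HSD), an additive fold-change epistasis model with a
    pathway-membership classifier, delta-delta-Ct qPCR relative
    quantification, preranked permutation set enrichment (ES/NES), and
    seeded synthetic-data generators with known ground truth for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    withr,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
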