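Package: droughtnet
Title: Gene-Phenotype Network Inference for Sunflower Drought Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline relating leaf transcriptome variation to
    morpho-physiological drought responses across sunflower genotypes under
    two drought scenarios (fixed-duration and fixed-intensity stress). It
    derives water-status statistics (FTSW, TTSW, ITW) from daily pot-weight
    series, classifies per-gene expression effects by two-way ANOVA with
    Bonferroni family-wise error control and residual-variance pooling,
    fits a sparse partial least squares regression of phenotypes on
    expression, thresholds latent-variate association scores into a
    bipartite gene-phenotype network, merges networks across scenarios, and
    tests independent (field) gene sets for enrichment in trait-linked
    network genes with hypergeometric statistics. A seeded synthetic-data
    generator emulating the 8-genotype x 2-treatment x 3-block design makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
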