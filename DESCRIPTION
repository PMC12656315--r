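Package: soilamend
Title: Soil Quality, Aggregate Stability and Microbiome Analysis for
    Acid-Soil Amendment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for field trials that evaluate
    alkaline amendments of acidic soils. Computes water-stable aggregate
    stability indices (R0.25, mean weight diameter, geometric mean
    diameter, fractal dimension), a PCA-based minimum-data-set soil
    quality index, amplicon community diversity and ordination statistics
    (Chao1, Shannon, Bray-Curtis, PCoA, PERMANOVA, ANOSIM, Mantel),
    cross-kingdom co-occurrence networks with Zi-Pi keystone
    classification, partial least squares path modeling with
    goodness-of-fit, and two-way ANOVA with Duncan's multiple range test.
    Ships a synthetic study generator with known ground truth so the full
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
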