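Package: phyllotorsion
Title: Divergence-Angle Statistics, Stem-Torsion Modelling and
    Bulk-Segregant Variant Filtering for Plant Phyllotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of phyllotactic patterns in rosettes,
    inflorescences and meristems: circular binning of consecutive divergence
    angles into 2D heatmaps with a golden-angle window, chirality assignment
    and normalization, M-shaped motif detection, and per-leaf-pair angle
    profiles. Includes a trigonometric stem-torsion displacement model and a
    seeded generative simulator of in-silico inflorescence populations with
    parameter sweeps, a statistics harness (chirality-stratified
    divergence-versus-internode binned regression, Welch/Wilcoxon/ANOVA-Tukey
    comparisons, two-proportion z-tests with continuity correction,
    Benjamini-Hochberg adjustment, growth metrics), a bulk-segregant-analysis
    filter for mapping recessive EMS alleles from two-pool allele depths
    under Haldane linkage, and synthetic-data generators for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
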