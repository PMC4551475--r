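Package: myodev
Title: Regional Rare-Variant Association and Gene-Environment Trajectory
    Models for Refractive Error
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how low-frequency genetic variants and
    visual environment shape refractive eye development. Provides a
    synthetic cohort generator (linkage-disequilibrium genotype blocks,
    questionnaire exposures, longitudinal spherical-equivalent
    trajectories), single-SNP dosage regression scans with QQ
    computation, phenotype-permutation regional enrichment tests
    (minimum-p and low-percentile statistics), Kolmogorov-Smirnov
    region comparison for summary statistics, a linear mixed model for
    refractive trajectories with genotype-by-reading-by-age
    interactions, cross-sectional logistic and linear gene-environment
    models, and a two-class expression ranking metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
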