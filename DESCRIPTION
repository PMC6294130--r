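Package: ibescape
Title: Isolation-by-Distance and Isolation-by-Environment Landscape Genomics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale landscape-genomics pipeline for partitioning genetic
    differentiation into geographic (isolation-by-distance, IBD) and
    ecological (isolation-by-environment, IBE) components in a multi-locality,
    multi-habitat sampling design. Provides GBS-style SNP filtering,
    identity-by-state kinship and linkage-disequilibrium pruning, principal
    coordinates analysis, hierarchical AMOVA, the Evanno delta-K statistic,
    genome-environment association scans with fixed-effect (GLM) and
    kinship mixed-model (EMMA/P3D) families, Weir-Cockerham pairwise F_ST,
    Rousset linearization, island-model migrant-number estimation with
    migration-network group contrasts, permutation Mantel tests over
    geographic and habitat-rank distance matrices, and a Balding-Nichols /
    Wright-Fisher synthetic-data generator that reproduces the statistical
    structure the analysis assumes, so every stage is verifiable on simulated
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    geosphere,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
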