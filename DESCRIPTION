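Package: landgen
Title: Individual-Based Landscape Genomics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for individual-based landscape genomics:
    reads variant calls (VCF) and sampling coordinates, performs genotype
    preprocessing (LD pruning, median and population-structure-based
    imputation), infers spatially regularized ancestry coefficients with
    kriged cluster maps, maps genetic diversity (heterozygosity, nucleotide
    diversity, rarefied allelic richness) in moving windows, quantifies
    isolation by distance, environment and resistance with multiple matrix
    regression (MMRR) and generalized dissimilarity modelling (GDM), and
    scans for genotype-environment associations with redundancy analysis
    (RDA/pRDA) and ridge latent factor mixed models (LFMM). Includes a
    synthetic-data generator with known population structure so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    mgcv,
    pracma,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
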