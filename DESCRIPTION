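Package: haploqtl
Title: Local Haplotype Clustering and Ancestral-Allele QTL Mapping in
    Multi-Cross Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters the parent lines of connected multi-cross designs
    along the genome using a kinship-extended sliding-window haplotype
    similarity score, and uses the per-locus clusters ("ancestral
    alleles") to collapse the parameters of a connected marker-regression
    QTL model. Includes equilibrium and founder-mosaic null samplers for
    clustering thresholds, hidden-Markov-model pair classification,
    multipoint parental-origin genotype probabilities for F2, F3,
    backcross and RIL families, permutation genome-wide thresholds, an
    iterative cofactor QTL detection procedure, and a simulation
    framework to compare the power and mapping precision of the
    per-parent and per-cluster models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    xml2
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
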