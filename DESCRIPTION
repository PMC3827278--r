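Package: arrayphylo
Title: Phylogenies from SNP Array Genotypes and Hybridization Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for distance-based phylogeny reconstruction from SNP
    genotyping arrays, comparing the classical genotype-call route
    (quality filtering, LD pruning, Weir-Cockerham pairwise FST,
    neighbor joining) against a hybridization-intensity route that
    treats normalized two-channel intensities as quantitative genotypes
    (per-SNP summary statistics, per-species medians, Euclidean
    distances). Includes a synthetic ascertained-array generator with a
    known species tree, Balding-Nichols allele-frequency drift,
    discovery-panel ascertainment and divergence-dependent probe
    affinity decay, plus Mantel tests, classical MDS, bipartition
    (Robinson-Foulds/Penny-Hendy) tree distances, and diagnostics for
    SNP ascertainment bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
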