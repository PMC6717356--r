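Package: v1rpipe
Title: Vomeronasal Type-1 Receptor Repertoire Mining, Comparative
    Phylogenetics and Two-Population Genetics
Version: 0.1.0
Authors@R:
    person("Repertoire", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A desk-scale reimplementation of a three-part analysis of
    vomeronasal type-1 receptor (V1R) gene family evolution in rodents:
    homology-based mining of V1R-like loci from genome assemblies with
    intact/partial/pseudogene classification; phylogenetically independent
    contrasts correlating repertoire size with a binary
    subterranean/superterranean lifestyle; and per-locus population
    genetics of receptor alleles sampled from two populations (nucleotide
    diversity, Watterson's theta, Tajima's D, Fu and Li's D* with
    coalescent significance, Hudson's FST, the Snn nearest-neighbour
    permutation test, per-SNP Fisher tests with FDR adjustment, and
    transmembrane-topology mapping of differentiated nonsynonymous SNPs).
    A seeded synthetic-data generator produces genomes with implanted
    genes, Brownian-motion traits on dated trees, and two-population
    coalescent alignments, so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
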