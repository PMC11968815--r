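Package: proteogut
Title: Lineage-Aware Gene Prediction Consensus and Protein Ecology for
    Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("proteogut", "developers", email = "dev@proteogut.org",
           role = c("aut", "cre"))
Description: Taxonomy-routed, genetic-code-correct open reading frame
    calling and multi-tool gene-prediction consensus merging for
    assembled metagenomic contigs; construction of non-redundant protein
    catalogues by greedy identity/coverage clustering with small-protein
    cluster discovery; and statistical protein-ecology analysis across
    human gut samples (prevalence and host-metadata association via
    Fisher's exact test with Benjamini-Hochberg correction,
    function-positive fractions, taxonomic range) together with
    metatranscriptomic expression quantification (aligned fraction,
    RPKM, expression prevalence). Includes a seeded synthetic-data
    generator so every analysis is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
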