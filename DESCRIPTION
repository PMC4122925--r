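Package: archpan
Title: Archaeal Pangenome Construction and Interdomain HGT Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pangenomes for uncultured marine archaeal lineages from
    fosmid-sized genome fragments and infers bacteria-to-archaea horizontal
    gene transfer (HGT) from gene-tree topology. Ortholog clusters are
    classified into archaeal core, lineage-specific core and shell genes;
    transfers are timed as early (at the base of a lineage) or late (after
    its diversification) and attributed to donor phyla. Supporting
    statistics include tetranucleotide z-score composition profiles with
    principal component analysis, quality-threshold clustering of taxon
    profiles, synteny blocks with bounding-couple occurrence matrices,
    codon usage tables and the codon adaptation index, and genome-equivalent
    estimates from single-copy marker genes. A synthetic fosmid-community
    generator with planted gene origin classes makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
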