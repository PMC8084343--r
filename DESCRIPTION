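Package: galcodon
Title: Codon Optimization of Metabolic Pathway Genes, Growth Phenotype, and
    Ecological Niche in Budding Yeasts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reverse-ecology pipeline linking translational selection on
    codon usage to growth phenotype and ecological niche in microbial
    genomes. Computes per-codon relative adaptiveness (wi) from tRNA gene
    copy numbers under a wobble-pairing model, gene-level species-specific
    tRNA adaptation indices (stAI), genome-normalized estAI ranks, and
    pathway-level optimization profiles (completeness, representative copy,
    contig clustering). Quantifies growth curves by maximum-slope rates with
    replicate voting and glucose normalization, relates optimization to
    growth by phylogenetically independent contrasts and PGLS regression,
    calibrates observed scores against random-codon null distributions, and
    tests niche and genome-wide orthology-group (KO) associations. Includes
    a synthetic-data generator with known ground truth so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
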