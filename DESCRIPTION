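Package: archvir
Title: Detection, Dereplication and Ecology of Archaeal Virus Contigs in
    Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies putative archaeal virus contigs in viral metagenomes
    by a majority-rules consensus over per-gene taxonomic annotations, using
    configurable thresholds on the archaeal-virus gene fraction and on BLASTp
    bit-score quality. Includes keyword-lexicon affiliation of gene lineages,
    readers for gene-per-contig annotation tables and BLAST tabular hits,
    greedy average-nucleotide-identity dereplication of contigs into viral
    populations, coverage-normalized abundance matrices with alpha- and
    beta-diversity statistics (richness, Shannon-Wiener, Pielou evenness,
    Bray-Curtis, Mantel test), and a seeded synthetic benchmark generator for
    measuring classifier sensitivity and accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
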