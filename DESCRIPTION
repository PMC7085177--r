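Package: dwmeta
Title: Comparative Metagenomics of Disinfected and Non-Disinfected Drinking Water Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing drinking-water metagenomes between
    systems that maintain a chlorine disinfectant residual and systems that do
    not. Implements negative-control-based scaffold decontamination (relative
    abundance and normalized coverage deviation classification), SSU rRNA
    taxonomic profiling with RPKM normalization, KEGG orthology and module
    abundance profiling with completeness-based filtering, MinHash sketch and
    Bray-Curtis community dissimilarities, exhaustive BioEnv environmental
    subset fitting, permutation tests on distance matrices, and detection-based
    categorization of metagenome-assembled genomes. A synthetic-study generator
    with planted group structure makes every stage testable end to end without
    external sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
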