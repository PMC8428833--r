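Package: panpav
Title: Map-to-Pan Gene Presence/Absence Variation Analysis for Pan-Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genic presence/absence variation (PAV) analysis in
    plant pan-genomes built with a map-to-pan strategy. Calls gene presence
    from breadth-of-coverage evidence (gene-body and CDS coverage thresholds),
    classifies genes into hardcore/softcore/shell/cloud frequency categories,
    estimates pan- and core-genome size by iterated rarefaction with
    saturation-model fits, derives PAV-based population structure (distances,
    PCA, neighbor-joining trees, Mantel comparison to SNP distances, clade
    gene-loss contrasts), extracts nonreference sequence from contig alignment
    summaries with redundancy and contaminant filtering, validates short-read
    PAV calls against long-read structural variants, and computes
    Nei-Gojobori (NG86) dN/dS. Includes a seeded synthetic-data generator
    producing ground-truthed pan-genomes, coverage profiles, structural
    variant calls and correlated SNP distance matrices so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    minpack.lm,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
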