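Package: azidomap
Title: Mutant Chemotyping and Mutagen-Aware Candidate-Gene Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for forward-genetics screens of sodium-azide
    mutagenized plant populations, built around the avenacin (oat root
    saponin) pathway use case. Provides mutagen-spectrum variant filtering
    (G:C to A:T transitions), cross-mutant sliding-window interval mapping
    and gene overlap, codon-level consequence annotation of coding
    substitutions, targeted-metabolomics PCA chemotyping with marker
    ranking and Mendelian segregation tests, and modified-cosine MS/MS
    molecular networking with neutral-loss annotation of glycosyl and acyl
    groups. A seeded synthetic-cohort generator emulates every input the
    pipeline consumes so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    igraph,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    generics,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
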