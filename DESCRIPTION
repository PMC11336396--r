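Package: dnadiag
Title: Diagnostic Nucleotide Barcodes, Clade Delimitation and Primer
    Screening for DNA-Based Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-based taxonomy of lineages known mainly from
    environmental rRNA sequences. Selects contiguous 20-30 base diagnostic
    barcodes with mismatch allowances from labelled ITS/LSU multiple
    sequence alignments, estimates within-species variability as the
    maximum pairwise proportion of differences, delimits candidate higher
    taxa on support-annotated phylogenies as least-inclusive clades under
    monophyly, support, phylogenetic-breadth and minimality criteria with
    provisional alphanumeric codes, and screens IUPAC-degenerate primers
    for terminal, near-terminal and central mismatches per lineage. A
    seeded simulator generates multi-species ITS+LSU alignments, trees
    and ground-truth records under the Jukes-Cantor model so that every
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
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
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
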