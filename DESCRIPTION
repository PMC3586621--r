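Package: skinktrace
Title: Phylogeographic Tracing of Intercepted Invasive Skinks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the origin of invasive lizards intercepted
    at national borders from mitochondrial DNA. Collapses aligned sequences
    to haplotypes, computes Tamura-Nei (TN93) corrected genetic distances
    and neighbour-joining trees, classifies each interception as a local
    resident, a within-country jump dispersal, or a new arrival direct from
    the native range, assigns source regions by nearest native-range
    haplotype, and summarises biosecurity interception records. A sequence
    simulator generates clade-structured reference panels and detection
    batches so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
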