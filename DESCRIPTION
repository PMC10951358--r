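Package: diagmark
Title: Chloroplast Barcode Markers for Species Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating closely related plant species from
    chloroplast sequence alignments. Implements sliding-window nucleotide
    diversity scans with divergence-hotspot calling, identification of
    species-specific SNP and insertion-deletion diagnostic markers from
    taxon-labelled alignments, pairwise evolutionary distances (p-distance,
    JC69, K2P, T3P, with optional gamma rate correction), neighbour-joining
    and UPGMA tree building with outgroup rooting and bootstrap support, and
    a monophyly-based discrimination success rate for single loci and locus
    combinations. A seeded simulator generates multi-locus, multi-accession
    alignments with planted diagnostic variants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
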