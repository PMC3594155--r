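Package: hicontact
Title: Hi-C Contact Map Analysis, Translocation Detection and Spatial
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for genome-conformation (Hi-C) data
    analysis at mapped-read-pair level: classification and filtering of
    paired-end mapping candidates into spatial contacts, binned intra- and
    inter-chromosomal contact matrices, sequential component normalization
    (SCN) and genomic-distance normalization, Pearson correlation and
    difference maps, Poisson contact significance, observed/expected
    inter-chromosomal enrichment, detection and matrix correction of
    reciprocal chromosomal translocations, and weighted spatial interaction
    networks over genes and transcription-factor binding sites with
    scale-free graph statistics. A seeded synthetic-data generator emulates
    distance-decay, compartment plaid structure, mapping artifacts and
    planted translocations so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    rlang,
    readr,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
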