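Package: virnaprof
Title: Virus-Derived Small RNA Profiling and piRNA Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Profiling of virus-derived small interfering RNAs (vsiRNAs) and
    PIWI-interacting RNAs (vpiRNAs) from small RNA sequencing libraries of
    virus-infected insects. Provides a small RNA library simulator emulating
    multi-virus co-infections, adapter and quality trimming, short-read
    alignment to viral genomes allowing at most one mismatch (pigeonhole
    seeding), strand-resolved size distributions and 5'-end coverage profiles
    with hotspot detection, reads-per-million normalization, the
    vpiRNA:vsiRNA proportion statistic, positional nucleotide frequency
    matrices, 1U/10A bias tests, and ping-pong 5'-overlap analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
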