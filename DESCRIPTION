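Package: oligostore
Title: Hidden-Addressing Fountain Codec for DNA Data Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes arbitrary binary payloads into short, biochemically
    constrained DNA sequences using a grouped Luby-transform (fountain) code
    in which one of the data droplets doubles as the sequence index
    ("hidden addressing"), and decodes shuffled, error-containing pools back
    to the original bytes. Each 192-nt sequence carries eight 23-nt
    constraint-filtered fragments (45-55% GC, no homopolymer runs of three
    or more) plus Reed-Solomon parity. Includes the evaluation toolkit for
    such codes: k-mer Jaccard self-similarity, word-match dotplots, windowed
    GC statistics, redundancy and net information density, and a simple
    Illumina-like single-end read simulator with coverage reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    rlang,
    ggplot2,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
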