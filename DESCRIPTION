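Package: degradomeR
Title: Degradome (PARE) Sequencing Analysis of miRNA-Guided Cleavage
Version: 0.1.0
Authors@R:
    person("Degradome", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Identification of microRNA cleavage targets from degradome
    (parallel analysis of RNA ends, PARE) sequencing libraries. Implements
    quality and length filtering of degradome reads, exact-match mapping
    onto a transcript set, plant-style miRNA:mRNA complementarity scoring
    with a penalty gate and a paired-cleavage-site rule, CleaveLand-style
    category 0-4 classification of cleavage signatures, per-library
    normalised abundance (tags per 100 million mapped reads), empirical
    p-values from composition-preserving miRNA shuffles, target plots,
    tissue-partition set logic across libraries, and annotation-set
    comparison between datasets. A seeded synthetic-library generator with
    known planted cleavage events supports end-to-end testing without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
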