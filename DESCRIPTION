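Package: stwintrons
Title: Detection and Evolutionary Analysis of Spliceosomal Twin Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spliceosomal twin introns ("stwintrons") in nucleotide
    sequence under a configurable U2 splice-site motif grammar
    (donor, lariat branch point, acceptor), simulates their obligatory
    two-step excision together with standard intron splicing, maps intron
    positions onto protein multiple alignments to identify homologous
    intron sites across species, and infers minimal-cost gain/loss
    histories of stwintron and intron states on a rooted phylogeny under
    a Dollo-style Sankoff dynamic program. A deterministic synthetic-data
    generator instantiates intron and stwintron motif skeletons and
    simulates orthologue families with planted site states, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
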