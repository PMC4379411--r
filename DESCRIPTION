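Package: splicevo
Title: Evolution of Unproductive Splicing in Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of unproductive splicing (alternative
    splicing coupled to nonsense-mediated mRNA decay) across a duplicating
    gene family. Maps intron positions onto protein alignments and treats
    them as binary phylogenetic characters, calls cassette-exon, intron
    retention and early-polyadenylation events from spliced EST alignments,
    classifies event isoforms as NMD targets with the 50-nt junction rule,
    reconstructs gain/loss histories of poison exons by Dollo parsimony and
    classifies family histories as single-origin, independent, or
    replacement, detects ultraconserved perfect-identity runs, and ships a
    gene-family evolution simulator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
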