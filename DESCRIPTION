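Package: bhlhcensus
Title: Genome-Wide Census of Basic Helix-Loop-Helix Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide surveys of basic helix-loop-helix (bHLH)
    transcription factors from unannotated genomic contigs. Candidate bHLH
    motifs are found by translated six-frame profile scanning with
    intron-aware segment chaining, validated by a two-stage conserved-site
    filter over 19 canonical bHLH alignment positions, and assigned to
    families by in-group phylogenetic analysis (neighbor joining on a PAM250
    step matrix, branch-and-bound maximum parsimony, and an ML-surrogate
    method over JTT maximum-likelihood distances) with bootstrap-supported
    monophyly tests. Intron locations and lengths within motifs are derived
    from genomic coding segments, and aggregate survey reports (family and
    high-order group counts, intron summaries, annotation audits) are
    produced. A synthetic-genome generator with planted, family-labelled,
    intron-split bHLH genes provides a fully offline test bed, and
    transcriptions of a published giant-panda bHLH survey are included as
    packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
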