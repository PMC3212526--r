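# Shared fixtures built in code. The synthetic reference set is deterministic
# for its seed, so building it once per test run is safe and cheap.

test_refset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_reference_set()
    cache
  }
})

# A tiny two-family reference set with hand-controllable divergence, for
# orthology tests that need full control over distances.
tiny_refset <- function(seed = 123, member_div = 0.25) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    protoA <- mutate_motif(bhlh_consensus(), 0.35)
    protoB <- mutate_motif(bhlh_consensus(), 0.35)
    refs <- data.frame(
      id = c("famA_m1", "famA_m2", "famA_m3", "famB_m1", "famB_m2", "famB_m3"),
      family = rep(c("FamA", "FamB"), each = 3),
      group = rep(c("A", "B"), each = 3),
      sequence = c(mutate_motif(protoA, member_div),
                   mutate_motif(protoA, member_div),
                   mutate_motif(protoA, member_div),
                   mutate_motif(protoB, member_div),
                   mutate_motif(protoB, member_div),
                   mutate_motif(protoB, member_div)),
      stringsAsFactors = FALSE)
    attr(refs, "region_template") <- bhlh_region_template()
    class(refs) <- c("bhlh_refset", "data.frame")
    list(refs = refs,
         catalog = structure(data.frame(family = c("FamA", "FamB"),
                                        group = c("A", "B"),
                                        stringsAsFactors = FALSE),
                             class = c("family_catalog", "data.frame")),
         outgroup = data.frame(id = "outg",
                               sequence = mutate_motif(bhlh_consensus(), 0.55),
                               stringsAsFactors = FALSE))
  })
}

# Random amino-acid string helper.
random_aa <- function(n) paste(sample(bhlhcensus:::AA_ALPHABET, n, TRUE),
                               collapse = "")

# Independent splicing oracle: extract recorded segments from a contig,
# splice in reading order and translate with Biostrings.
splice_translate <- function(contig, segments, strand) {
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    a <- segments$start[i]; b <- segments$end[i]
    s <- substring(contig, min(a, b), max(a, b))
    if (strand == "-") s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, "")
  as.character(Biostrings::translate(Biostrings::DNAString(
    paste(parts, collapse = ""))))
}
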