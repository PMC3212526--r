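test_that("coordinate gaps reproduce the published single-intron examples", {
  # plus strand, the 8,330 bp loop intron
  gs <- data.frame(gene_id = "GpAth6", contig = "NW_003218843.1",
                   start = c(61194, 69602), end = c(61271, 69682))
  out <- segments_to_introns(gs)
  expect_equal(out$length, 8330)
  # minus strand (descending coordinates), the 6,972 bp basic intron
  gs2 <- data.frame(gene_id = "GpSRC1", contig = "NW_003217319.1",
                    start = c(2757930, 2750940), end = c(2757913, 2750785))
  expect_equal(segments_to_introns(gs2)$length, 6972)
})

test_that("single segments, multi-contig structures and overlaps are handled", {
  one <- data.frame(gene_id = "g", contig = "c", start = 10, end = 100)
  expect_equal(nrow(segments_to_introns(one)), 0)
  two_ctg <- data.frame(gene_id = "g", contig = c("c1", "c2"),
                        start = c(10, 5), end = c(100, 50))
  out <- segments_to_introns(two_ctg)
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "multi_contig"))
  overlap <- data.frame(gene_id = "g", contig = "c",
                        start = c(10, 90), end = c(100, 200))
  expect_error(segments_to_introns(overlap), "overlap")
})

test_that("intron regions follow the interrupted codon through the region
           map, with the downstream tie-break", {
  gs <- data.frame(gene_id = "g", contig = "c",
                   start = c(1, 200, 400), end = c(39, 280, 462))
  attr(gs, "region_map") <- bhlh_region_template()
  out <- segments_to_introns(gs)
  # 39 bp = 13 codons -> downstream residue 14 = helix1;
  # 39 + 81 bp = 40 codons -> downstream residue 41 = loop
  expect_equal(out$region, c("helix1", "loop"))
  expect_equal(out$length, c(160, 119))
})

test_that("the packaged coding-region table parses, validates, and carries
           the documented anomalies only", {
  parsed <- parse_table2()
  expect_equal(nrow(parsed$genes), 107)
  expect_equal(nrow(parsed$introns), 70)
  # every checked row not on the skip-list validates exactly
  skip <- table2_anomalies()$coordinate
  flagged <- parsed$introns[!parsed$introns$valid, c("gene_id", "index")]
  expect_equal(flagged$gene_id, skip$gene)
  expect_equal(flagged$index, skip$intron)
  # spot checks against the printed record
  expect_equal(parsed$introns$derived[parsed$introns$gene_id == "GpParaxis"],
               29249)
  mad1 <- parsed$introns[parsed$introns$gene_id == "GpMad1", ]
  expect_equal(mad1$length, c(4015, 14277, 1545))
  # the split-over-two-contigs member yields no intron and keeps its note
  hen2 <- parsed$genes[parsed$genes$gene_id == "GpHen2", ]
  expect_true(hen2$multi_contig)
  expect_match(hen2$note, "two separate contigs")
  expect_false("GpHen2" %in% parsed$introns$gene_id)
})

test_that("an undocumented coordinate mismatch raises a validation error", {
  t2 <- read.delim(census_fixture("table2_structures.tsv"),
                   colClasses = "character")
  t2$start[t2$gene == "GpAth6"][2] <- "69700"   # corrupt the second segment
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(t2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_table2(path), "GpAth6")
})

test_that("the intron summary reproduces the survey statistics", {
  parsed <- parse_table2()
  s <- summarize_introns(parsed$introns, genes = parsed$genes$gene_id)
  expect_equal(s$members_with_introns, 47)
  expect_equal(unname(s$histogram), c(26L, 19L, 2L))
  expect_equal(s$total_introns, 70)
  expect_equal(s$max_length, 45217)
  expect_equal(s$mean_length, 4393)
  expect_equal(s$by_count$one_intron$basic, 13)
  expect_equal(s$by_count$one_intron$loop, 12)
  expect_equal(s$by_count$one_intron$helix2, 1)
  expect_equal(s$by_count$two_introns[["basic+loop"]], 15)
  expect_equal(s$by_count$two_introns[["basic+helix2"]], 3)
  expect_equal(s$by_count$two_introns[["helix1+helix2"]], 1)
  # conservation: histogram weights sum to the intron total
  expect_equal(sum(s$histogram * (1:3)), s$total_introns)
})

test_that("empty input produces an all-zero summary", {
  s <- summarize_introns(data.frame(gene_id = character(), index = integer(),
                                    length = numeric(), region = character()))
  expect_equal(s$members_with_introns, 0)
  expect_equal(s$total_introns, 0)
  expect_equal(s$max_length, 0)
})

test_that("derived introns equal the synthetic plan on both strands, and
           survive reverse-complementing the contig", {
  rs <- test_refset()
  g <- generate_genome(rs, n_genes = 6, seed = 13)
  for (gid in unique(g$truth$gene_id)) {
    tr <- g$truth[g$truth$gene_id == gid, ]
    gs <- data.frame(gene_id = gid, contig = tr$contig,
                     start = tr$start, end = tr$end)
    attr(gs, "region_map") <- bhlh_region_template()
    out <- segments_to_introns(gs)
    plan <- g$introns[g$introns$gene_id == gid, ]
    expect_equal(out$length, plan$length)
    expect_equal(out$region, plan$region)
    # mirror the contig: coordinates flip, intron lengths and regions hold
    L <- nchar(g$contigs[[tr$contig[1]]])
    gs2 <- data.frame(gene_id = gid, contig = tr$contig,
                      start = L - tr$start + 1, end = L - tr$end + 1)
    attr(gs2, "region_map") <- bhlh_region_template()
    out2 <- segments_to_introns(gs2)
    expect_equal(out2$length, plan$length)
    expect_equal(out2$region, plan$region)
  }
})
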