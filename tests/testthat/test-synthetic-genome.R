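test_that("mutate_motif honours rate 0, full rate with protection, and the
           binomial substitution law", {
  m <- bhlh_consensus()
  expect_equal(mutate_motif(m, 0, seed = 1), m)
  full <- mutate_motif(m, 1, protect_conserved = TRUE, seed = 2)
  diffs <- which(strsplit(m, "")[[1]] != strsplit(full, "")[[1]])
  expect_length(diffs, 60 - 19)
  expect_length(intersect(diffs, default_conserved_sites()), 0)
  # mean substitution count over replicates vs binomial expectation
  set.seed(42)
  n_rep <- 4000
  counts <- vapply(seq_len(n_rep), function(i) {
    x <- mutate_motif(m, 0.1, protect_conserved = FALSE)
    sum(strsplit(m, "")[[1]] != strsplit(x, "")[[1]])
  }, 0)
  expectation <- 60 * 0.1
  se <- sqrt(60 * 0.1 * 0.9 / n_rep)
  expect_lt(abs(mean(counts) - expectation), 3 * se)
})

test_that("realize_gene reproduces planned intron geometry exactly", {
  rs <- test_refset()
  motif <- rs$refs$sequence[1]
  set.seed(3)
  bg <- bhlhcensus:::random_dna(12000)
  # intron-free gene: one segment translating back to the motif
  spec0 <- list(gene_id = "g0", family = "f", motif_seq = motif,
                intron_plan = data.frame(codon = integer(), length = integer()),
                strand = "+", contig_id = "c", insertion_offset = 101L)
  rg0 <- realize_gene(spec0, bg)
  expect_equal(nrow(rg0$segments), 1)
  expect_equal(splice_translate(rg0$contig, rg0$segments, "+"), motif)
  # the published single-intron geometry: an 8,330 bp loop intron leaves a
  # coordinate gap of exactly 8,330 between the two coding segments
  spec1 <- list(gene_id = "g1", family = "f", motif_seq = motif,
                intron_plan = data.frame(codon = 30L, length = 8330L),
                strand = "+", contig_id = "c", insertion_offset = 101L)
  rg1 <- realize_gene(spec1, bhlhcensus:::random_dna(12000))
  expect_equal(nrow(rg1$segments), 2)
  expect_equal(rg1$segments$start[2] - rg1$segments$end[1] - 1L, 8330L)
  expect_equal(splice_translate(rg1$contig, rg1$segments, "+"), motif)
})

test_that("splice-translate inversion and intron arithmetic hold on both
           strands", {
  rs <- test_refset()
  set.seed(11)
  for (strand in c("+", "-")) for (rep in 1:5) {
    motif <- rs$refs$sequence[sample(nrow(rs$refs), 1)]
    plan <- data.frame(codon = sort(sample(9:52, 2)), length = c(88, 1500))
    if (diff(plan$codon) < 8) next
    spec <- list(gene_id = "g", family = "f", motif_seq = motif,
                 intron_plan = plan, strand = strand, contig_id = "c",
                 insertion_offset = 151L)
    rg <- realize_gene(spec, bhlhcensus:::random_dna(3000))
    expect_equal(splice_translate(rg$contig, rg$segments, strand), motif)
    gaps <- abs(rg$segments$start[-1] - rg$segments$end[-nrow(rg$segments)]) - 1L
    expect_equal(gaps, plan$length)
  }
})

test_that("gene placement is validated", {
  motif <- bhlh_consensus()
  spec <- list(gene_id = "g", family = "f", motif_seq = motif,
               intron_plan = data.frame(codon = integer(), length = integer()),
               strand = "+", contig_id = "c", insertion_offset = 50L)
  expect_error(realize_gene(spec, strrep("A", 100)), "too short")
  expect_error(realize_gene(spec, strrep("A", 1000),
                            occupied = rbind(c(40L, 90L))),
               "placement")
  bad <- spec
  bad$intron_plan <- data.frame(codon = 10L, length = 30L)
  expect_error(realize_gene(bad, strrep("A", 1000)), ">= 60")
})

test_that("generate_genome is deterministic, supports n_genes = 0, and its
           truth matches the derived introns", {
  rs <- test_refset()
  g1 <- generate_genome(rs, n_genes = 3, seed = 9)
  g2 <- generate_genome(rs, n_genes = 3, seed = 9)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(g1$truth, g2$truth)
  g0 <- generate_genome(rs, n_genes = 0, seed = 9)
  expect_equal(nrow(g0$truth), 0)
  expect_equal(names(g0$contigs), "ctg_bg")
  # truth segment arithmetic reproduces the planned intron lengths
  for (gid in unique(g1$truth$gene_id)) {
    tr <- g1$truth[g1$truth$gene_id == gid, ]
    gaps <- abs(tr$start[-1] - tr$end[-nrow(tr)]) - 1L
    expect_equal(gaps, g1$introns$length[g1$introns$gene_id == gid])
    expect_equal(splice_translate(g1$contigs[[tr$contig[1]]],
                                  tr, tr$strand[1]),
                 unname(g1$motifs[gid]))
  }
})

test_that("ground truth exports parse back via rtracklayer", {
  rs <- test_refset()
  g <- generate_genome(rs, n_genes = 2, seed = 5)
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(g, gff_path = gff, tsv_path = tsv)
  gr <- rtracklayer::import(gff)
  cds <- gr[gr$type == "CDS"]
  expect_equal(length(cds), nrow(g$truth))
  lo <- pmin(g$truth$start, g$truth$end)
  expect_setequal(GenomicRanges::start(cds), lo)
  mirror <- read.delim(tsv)
  expect_equal(nrow(mirror), nrow(g$truth))
  expect_equal(mirror$gene, g$truth$gene_id)
})
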