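test_that("categorization reproduces the survey's outcome patterns", {
  t1 <- load_table1()
  cat1 <- categorize_table1(t1)
  pick <- function(g) cat1$category[cat1$gene == g]
  # all three methods strong on the same partner
  expect_equal(pick("GpAsh1"), 1L)
  # NJ and ML strong, MP weak (21)
  expect_equal(pick("GpTCF4"), 2L)
  # only NJ supports; MP and ML fail family-level monophyly
  expect_equal(pick("GpTF12"), 3L)
  # whole-protein fallback rows
  expect_true(all(cat1$category[cat1$whole_protein == 1] == 4L))
  # the first category holds exactly the survey's 83 members
  expect_equal(sum(cat1$category == 1), 83)
})

test_that("categorize is total and monotone in bootstrap support", {
  set.seed(61)
  mk <- function(b, f) data.frame(
    method = c("NJ", "MP", "ML"),
    partner = ifelse(is.na(b), NA_character_, "p"),
    bootstrap = b, flag = ifelse(is.na(b), f, "mono_with_partner"),
    stringsAsFactors = FALSE)
  for (i in 1:100) {
    b <- ifelse(runif(3) < 0.25, NA, sample(0:100, 3, TRUE))
    f <- sample(c("n/m", "n/m*"), 3, TRUE)
    res <- categorize(mk(b, f))
    expect_true(res$category %in% 1:4)
    # raising one bootstrap value never demotes the category
    j <- sample(3, 1)
    if (!is.na(b[j]) && b[j] < 100) {
      b2 <- b; b2[j] <- 100
      expect_lte(categorize(mk(b2, f))$category, res$category)
    }
  }
  expect_equal(categorize(mk(c(NA, NA, NA), rep("n/m", 3)))$category, 4L)
})

test_that("a candidate identical to a reference partners with it at full NJ
           support", {
  rs <- tiny_refset()
  seqs <- c(cand = rs$refs$sequence[2],
            stats::setNames(rs$refs$sequence, rs$refs$id),
            stats::setNames(rs$outgroup$sequence, rs$outgroup$id))
  fam <- stats::setNames(rs$refs$family, rs$refs$id)
  res <- run_ingroup_analysis("cand", seqs, rs$outgroup$id, fam,
                              orthology_config(nj_reps = 100, mp_reps = 50,
                                               ml_reps = 50, seed = 2))
  nj <- res[res$method == "NJ", ]
  expect_equal(nj$partner, "famA_m2")
  expect_equal(nj$bootstrap, 100)
})

test_that("a candidate equally related to all family members flags n/m*", {
  # the family members share a derived core (they cluster together) and the
  # candidate sits equidistantly outside that cluster: no single member is
  # closer, but candidate + family form a clade
  set.seed(77)
  proto <- mutate_motif(bhlh_consensus(), 0.3)
  free <- setdiff(seq_len(60), default_conserved_sites())
  mut_at <- function(seq, pos) {
    r <- strsplit(seq, "")[[1]]
    for (p in pos) r[p] <- setdiff(bhlhcensus:::AA_ALPHABET, r[p])[1]
    paste(r, collapse = "")
  }
  core <- mut_at(proto, free[1:6])
  members <- c(m1 = mut_at(core, free[7:8]), m2 = mut_at(core, free[9:10]),
               m3 = mut_at(core, free[11:12]))
  cand_seq <- mut_at(proto, free[13:18])
  other <- mutate_motif(bhlh_consensus(), 0.35, seed = 5)
  seqs <- c(cand = cand_seq, members,
            o1 = mutate_motif(other, 0.1, seed = 6),
            o2 = mutate_motif(other, 0.1, seed = 7),
            outg = mutate_motif(bhlh_consensus(), 0.55, seed = 8))
  fam <- c(m1 = "FamX", m2 = "FamX", m3 = "FamX", o1 = "FamY", o2 = "FamY")
  res <- run_ingroup_analysis("cand", seqs, "outg", fam,
                              orthology_config(nj_reps = 100, mp_reps = 50,
                                               ml_reps = 50, seed = 3))
  nj <- res[res$method == "NJ", ]
  expect_true(is.na(nj$partner))
  expect_equal(nj$flag, "n/m*")
})

test_that("in-group selection returns the family surrounding the candidate", {
  rs <- test_refset()
  fam <- rs$refs$family[10]
  cand <- c(cand = mutate_motif(rs$refs$sequence[10], 0.03, seed = 9))
  gt <- global_reference_tree(cand, rs)
  sel <- select_ingroup("cand", gt, rs$refs, rs$outgroup$id)
  expect_true(all(rs$refs$id[rs$refs$family == fam] %in% sel))
  expect_lte(length(sel), 6)
  expect_error(select_ingroup("nope", gt, rs$refs, rs$outgroup$id),
               "not in the global tree")
})

test_that("assign_orthologs recovers planted families and the whole-protein
           fallback resolves category-4 candidates", {
  rs <- tiny_refset()
  set.seed(91)
  cand <- c(c1 = mutate_motif(rs$refs$sequence[1], 0.05),
            c2 = mutate_motif(rs$refs$sequence[5], 0.05))
  cfg <- orthology_config(nj_reps = 100, mp_reps = 50, ml_reps = 50, seed = 4)
  calls <- assign_orthologs(cand, rs, cfg)
  expect_equal(calls$family, c("FamA", "FamB"))
  expect_true(all(calls$category <= 2))
  # a motif-level stranger (a copy of the distant outgroup, so no method
  # can pair it with any reference) whose whole protein carries the family
  # signal
  stranger <- c(cx = rs$outgroup$sequence)
  wp <- c(stats::setNames(paste0(strrep("Q", 30), rs$refs$sequence,
                                 strrep("S", 30)), rs$refs$id),
          stats::setNames(paste0(strrep("K", 30), rs$outgroup$sequence,
                                 strrep("D", 30)), rs$outgroup$id),
          cx = paste0(strrep("Q", 30), rs$refs$sequence[3], strrep("S", 30)))
  calls2 <- assign_orthologs(stranger, rs, cfg, whole_proteins = wp)
  expect_equal(calls2$category, 4L)
  expect_equal(calls2$family, "FamA")
})
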