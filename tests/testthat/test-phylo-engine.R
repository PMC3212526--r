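test_that("the PAM250 step matrix is a valid cost table", {
  d <- step_matrix_pam250()
  expect_equal(dim(d), c(20, 20))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
})

test_that("step-matrix distances match a per-column brute-force summation", {
  cost <- step_matrix_pam250()
  set.seed(3)
  seqs <- stats::setNames(vapply(1:6, function(i) random_aa(40), ""),
                          paste0("s", 1:6))
  # plant some gaps
  substring(seqs[2], 5, 7) <- "---"
  substring(seqs[3], 1, 1) <- "X"
  D <- pairwise_distances(seqs, cost)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:5) for (j in (i + 1):6) {
    a <- strsplit(seqs[[i]], "")[[1]]; b <- strsplit(seqs[[j]], "")[[1]]
    ok <- a %in% rownames(cost) & b %in% rownames(cost)
    manual <- mean(vapply(which(ok), function(k) cost[a[k], b[k]], 0))
    expect_equal(D[i, j], manual)
  }
  expect_error(pairwise_distances(c(a = "---", b = "AR-", c = "ARN")), "a")
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  D <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("a", "b", "c")]), c(3, 2, 6))
  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers random additive trees exactly, matching ape", {
  set.seed(11)
  for (n in c(4, 5, 7, 10)) for (rep in 1:5) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    D <- ape::cophenetic.phylo(tr)
    got <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), got), 0,
                 ignore_attr = TRUE)
    # branch lengths are recovered: path lengths match the input metric
    expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    # and the independent implementation agrees on topology
    expect_equal(ape::dist.topo(ape::nj(D), got), 0, ignore_attr = TRUE)
  }
})

test_that("a four-taxon matrix resolves to the quartet favoured by the
           four-point condition", {
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  expect_true(is_monophyletic(ape::root(tr, "d", resolve.root = TRUE),
                              c("a", "b"), outgroup = "d"))
})

test_that("exact parsimony equals exhaustive enumeration and phangorn", {
  set.seed(19)
  for (n in c(4, 6)) for (rep in 1:3) {
    seqs <- stats::setNames(vapply(seq_len(n), function(i) random_aa(25), ""),
                            paste0("t", seq_len(n)))
    tr <- max_parsimony(seqs)
    best <- attr(tr, "pscore")
    # oracle: every topology via phangorn::allTrees + phangorn::fitch
    pd <- phangorn::phyDat(do.call(rbind, strsplit(seqs, "")), type = "AA")
    all_len <- vapply(phangorn::allTrees(n, tip.label = names(seqs)),
                      function(t) phangorn::fitch(t, pd), 0)
    expect_equal(best, min(all_len))
    expect_equal(parsimony_length(tr, seqs), best)
    expect_equal(phangorn::fitch(tr, pd), best)
  }
})

test_that("a four-taxon split site pattern yields the supporting topology", {
  seqs <- c(a = "AAAAA", b = "AAAAR", c = "RRRRA", d = "RRRRR")
  tr <- max_parsimony(seqs)
  expect_true(is_monophyletic(tr, c("a", "b"), outgroup = "d"))
  expect_equal(attr(tr, "pscore"),
               phangorn::fitch(tr, phangorn::phyDat(
                 do.call(rbind, strsplit(seqs, "")), type = "AA")))
})

test_that("adding a duplicate taxon leaves the parsimony length unchanged", {
  set.seed(29)
  seqs <- stats::setNames(vapply(1:5, function(i) random_aa(30), ""),
                          paste0("t", 1:5))
  l1 <- attr(max_parsimony(seqs), "pscore")
  seqs2 <- c(seqs, t5dup = seqs[["t5"]])
  l2 <- attr(max_parsimony(seqs2), "pscore")
  expect_equal(l1, l2)
  expect_error(max_parsimony(seqs, max_taxa = 4), "NJ-only")
})

test_that("branch and bound above the enumeration limit still finds the
           optimum", {
  set.seed(31)
  seqs <- stats::setNames(vapply(1:9, function(i) random_aa(15), ""),
                          paste0("t", 1:9))
  tr <- max_parsimony(seqs)
  pd <- phangorn::phyDat(do.call(rbind, strsplit(seqs, "")), type = "AA")
  opt <- phangorn::bab(pd, trace = 0)
  expect_equal(attr(tr, "pscore"),
               min(vapply(opt, function(t) phangorn::fitch(t, pd), 0)))
})

test_that("bootstrap gives full support to clean bipartitions and is
           seed-reproducible", {
  set.seed(41)
  a <- mutate_motif(bhlh_consensus(), 0.3, protect_conserved = FALSE)
  b <- mutate_motif(bhlh_consensus(), 0.3, protect_conserved = FALSE)
  seqs <- c(a1 = a, a2 = a, a3 = mutate_motif(a, 0.02, FALSE),
            b1 = b, b2 = mutate_motif(b, 0.02, FALSE))
  for (m in c("nj", "mp", "ml")) {
    bs <- bootstrap_support(seqs, m, replicates = 100, seed = 7)
    expect_true(all(bs$support >= 0 & bs$support <= 100))
    key <- bhlhcensus:::canonical_split(c("b1", "b2"), sort(names(seqs)))
    expect_equal(unname(bs$support[key]), 100)
    bs2 <- bootstrap_support(seqs, m, replicates = 100, seed = 7)
    expect_identical(bs$support, bs2$support)
  }
})

test_that("moderate-replicate bootstrap agrees with a high-replicate
           reference run", {
  set.seed(43)
  base <- mutate_motif(bhlh_consensus(), 0.3, protect_conserved = FALSE)
  seqs <- stats::setNames(vapply(1:5, function(i)
    mutate_motif(base, 0.15, FALSE), ""), paste0("t", 1:5))
  lo <- bootstrap_support(seqs, "nj", replicates = 200, seed = 1)
  hi <- bootstrap_support(seqs, "nj", replicates = 10000, seed = 2)
  common <- intersect(names(lo$support), names(hi$support))
  expect_gt(length(common), 0)
  expect_true(all(abs(lo$support[common] - hi$support[common]) <= 5))
})

test_that("the monophyly test agrees with ape on random eight-leaf trees", {
  set.seed(47)
  for (rep in 1:40) {
    tr <- ape::rtree(8)
    og <- sample(tr$tip.label, 1)
    taxa <- sample(setdiff(tr$tip.label, og), sample(2:6, 1))
    got <- is_monophyletic(tr, taxa, og)
    rooted <- ape::root(tr, og, resolve.root = TRUE)
    want <- ape::is.monophyletic(rooted, taxa)
    expect_equal(got, want)
  }
  tr <- ape::rtree(6)
  expect_true(is_monophyletic(tr, setdiff(tr$tip.label, "t1"), "t1"))
  expect_error(is_monophyletic(tr, "t2", "nope"), "outgroup")
})

test_that("trees round-trip through Newick with lengths and supports", {
  set.seed(53)
  base <- mutate_motif(bhlh_consensus(), 0.3, protect_conserved = FALSE)
  seqs <- stats::setNames(vapply(1:6, function(i)
    mutate_motif(base, 0.2, FALSE), ""), paste0("t", 1:6))
  bs <- bootstrap_support(seqs, "nj", replicates = 50, seed = 5)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(bs$tree, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(back, bs$tree), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(bs$tree$edge.length),
               tolerance = 1e-8)
  expect_setequal(back$node.label, bs$tree$node.label)
})
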