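profile_for_tests <- function() {
  rs <- test_refset()
  build_conserved_profile(rs$refs)
}

test_that("a candidate equal to the consensus maps onto itself with no gaps", {
  p <- profile_for_tests()
  aln <- align_to_profile(p$consensus, p)
  expect_false(aln$unalignable)
  expect_equal(aln$map, 1:60)
})

test_that("an internal deletion skips exactly the deleted columns", {
  p <- profile_for_tests()
  cand <- paste0(substring(p$consensus, 1, 29), substring(p$consensus, 33, 60))
  aln <- align_to_profile(cand, p)
  missing <- which(is.na(aln$map))
  expect_length(missing, 3)
  mapped <- aln$map[!is.na(aln$map)]
  expect_equal(mapped, seq_along(mapped))   # monotone, no residue reused
})

test_that("profile alignment scores match an independent dynamic-programming
           oracle", {
  p <- profile_for_tests()
  mat <- bhlhcensus:::score_matrix("BLOSUM62")
  go <- 10; ge <- 2
  # ends-free global alignment, affine gaps costing go + k * ge
  dp_score <- function(a, b) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
    M[1, ] <- 0; M[, 1] <- 0          # free end gaps
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
    max(M[n + 1, ], M[, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  }
  set.seed(17)
  for (i in 1:12) {
    cand <- mutate_motif(p$consensus, runif(1, 0, 0.4),
                         protect_conserved = FALSE)
    if (i %% 3 == 0)
      cand <- paste0(substring(cand, 1, 20), substring(cand, 26, 60))
    aln <- align_to_profile(cand, p)
    expect_equal(aln$score, dp_score(cand, p$consensus))
  }
})

test_that("site evaluation counts forced mismatches exactly", {
  p <- profile_for_tests()
  cons <- p$consensus
  expect_equal(evaluate_sites(align_to_profile(cons, p), p)$variations, 0)
  # knock out exactly 9 of the 19 sites with non-consensus residues
  res <- strsplit(cons, "")[[1]]
  for (s in p$sites[1:9]) {
    bad <- setdiff(bhlhcensus:::AA_ALPHABET,
                   c(p$residues[[match(s, p$sites)]], res[s]))
    res[s] <- bad[1]
  }
  ev <- evaluate_sites(align_to_profile(paste(res, collapse = ""), p), p)
  expect_equal(ev$variations, 9)
  expect_equal(ev$matches + ev$variations, 19)
})

test_that("random candidates evaluate identically to a per-site membership
           tally", {
  p <- profile_for_tests()
  set.seed(23)
  for (i in 1:10) {
    cand <- random_aa(60)
    aln <- align_to_profile(cand, p)
    ev <- evaluate_sites(aln, p)
    res <- strsplit(cand, "")[[1]]
    manual <- sum(vapply(seq_along(p$sites), function(k) {
      idx <- aln$map[p$sites[k]]
      !is.na(idx) && res[idx] %in% p$residues[[k]]
    }, TRUE))
    expect_equal(ev$matches, manual)
  }
})

test_that("the two filter stages apply the published thresholds", {
  evals <- data.frame(candidate_id = c("a", "b", "c", "d"),
                      matches = c(11L, 9L, 19L, 10L),
                      variations = c(8L, 10L, 0L, 9L))
  out <- apply_filter(evals)
  expect_setequal(out$accepted$candidate_id, c("a", "c"))
  expect_setequal(out$discarded$candidate_id, c("b", "d"))
  # matches 10 fails stage 1 (variations 9 is not < 9) though it would
  # survive stage 2; matches 9 fails both
  expect_equal(out$discarded$stage[out$discarded$candidate_id == "d"],
               "stage1")
})

test_that("increasing matches never flips a candidate to discarded", {
  set.seed(5)
  for (i in 1:50) {
    m <- sample(0:19, 1)
    e1 <- data.frame(candidate_id = "x", matches = m, variations = 19L - m)
    a1 <- nrow(apply_filter(e1)$accepted) == 1
    if (m < 19) {
      e2 <- data.frame(candidate_id = "x", matches = m + 1L,
                       variations = 18L - m)
      a2 <- nrow(apply_filter(e2)$accepted) == 1
      expect_true(a2 >= a1)
    }
  }
})

test_that("region delineation follows the template through insertions", {
  p <- profile_for_tests()
  aln <- align_to_profile(p$consensus, p)
  regions <- delineate_regions(aln, profile = p)
  expect_equal(regions, bhlh_region_template(), ignore_attr = TRUE)
  # a 3-residue insertion inside the loop grows only the loop
  cand <- paste0(substring(p$consensus, 1, 35), "GGG",
                 substring(p$consensus, 36, 60))
  r2 <- delineate_regions(align_to_profile(cand, p), profile = p)
  expect_equal(r2$loop[2] - r2$loop[1] + 1L,
               diff(bhlh_region_template()$loop) + 1L + 3L)
  expect_equal(r2$basic, bhlh_region_template()$basic)
  expect_equal(r2$helix2[2] - r2$helix2[1], 15L)
  # total coverage with no unassigned residue
  expect_equal(r2$basic[1], 1L)
  expect_equal(r2$helix2[2], nchar(cand))
})

test_that("unalignable candidates are flagged and refuse region maps", {
  p <- profile_for_tests()
  aln <- align_to_profile(random_aa(20), p)
  expect_true(aln$unalignable)
  expect_error(delineate_regions(aln, profile = p), "unalignable")
})
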