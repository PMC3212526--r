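# Phylogenetic substrate: PAM250 step-matrix distances, neighbor joining,
# column-resampling bootstrap, exact (enumeration / branch-and-bound) maximum
# parsimony, and the rooted monophyly test.

#' PAM250-derived amino-acid step matrix
#'
#' Integer cost table between amino-acid states derived from the Dayhoff
#' PAM250 log-odds matrix by `cost(a, b) = S(a,a) + S(b,b) - 2 S(a,b)`:
#' symmetric, zero on the diagonal, and nonnegative. This is the package's
#' fixed substitute for PAUP-style PAM250 step-matrix files.
#'
#' @return 20 x 20 integer matrix over the standard amino-acid alphabet.
#' @export
step_matrix_pam250 <- function() {
  S <- score_matrix("PAM250")[AA_ALPHABET, AA_ALPHABET]
  d <- outer(diag(S), diag(S), "+") - 2 * S
  storage.mode(d) <- "integer"
  d
}

#' Step-matrix pairwise distances between aligned sequences
#'
#' Distance between two aligned sequences is the mean per-column cost over
#' the columns where both carry a standard residue (gaps and ambiguity
#' characters are excluded).
#'
#' @param seqs Named character vector of aligned (equal-length) amino-acid
#'   strings.
#' @param cost Symmetric cost table (default [step_matrix_pam250()]).
#' @return Symmetric labelled distance matrix.
#' @export
pairwise_distances <- function(seqs, cost = step_matrix_pam250()) {
  m <- seq_matrix(seqs)
  labels <- names(seqs) %||% paste0("seq", seq_along(seqs))
  n <- nrow(m)
  valid <- matrix(m %in% rownames(cost), n)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok))
      stop("no comparable columns between '", labels[i], "' and '",
           labels[j], "'")
    D[i, j] <- D[j, i] <- mean(cost[cbind(m[i, ok], m[j, ok])])
  }
  D
}

# Per-pair per-column cost and validity arrays used for fast bootstrap
# distance recomputation (cost with 0 at invalid columns, plus a 0/1 mask).
pair_site_costs <- function(seqs, cost) {
  m <- seq_matrix(seqs)
  n <- nrow(m); L <- ncol(m)
  valid <- matrix(m %in% rownames(cost), n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), L); V <- matrix(0, nrow(pairs), L)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ok <- valid[i, ] & valid[j, ]
    V[k, ok] <- 1
    A[k, ok] <- cost[cbind(m[i, ok], m[j, ok])]
  }
  list(pairs = pairs, A = A, V = V, n = n)
}

pair_dist_from_weights <- function(pc, w) {
  num <- as.vector(pc$A %*% w)
  den <- as.vector(pc$V %*% w)
  if (any(den == 0)) den[den == 0] <- NA
  D <- matrix(0, pc$n, pc$n)
  D[pc$pairs] <- num / den
  D + t(D)
}

#' JTT maximum-likelihood pairwise distances
#'
#' Pairwise distances under the Jones-Taylor-Thornton model, each optimized
#' by maximum likelihood (via `phangorn::dist.ml`). This is the distance
#' backbone of the package's ML-surrogate tree method.
#'
#' @param seqs Named character vector of aligned amino-acid strings.
#' @return Symmetric labelled distance matrix.
#' @export
dist_ml_jtt <- function(seqs) {
  m <- seq_matrix(seqs)
  m[!(m %in% c(AA_ALPHABET, "B", "Z", "X", "-", "?"))] <- "X"
  rownames(m) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  pd <- phangorn::phyDat(m, type = "AA")
  as.matrix(phangorn::dist.ml(pd, model = "JTT"))
}

canonical_split <- function(set, all_labels) {
  if (all_labels[1] %in% set) set <- setdiff(all_labels, set)
  paste(sort(set), collapse = "|")
}

# Core NJ with smallest-index tie-breaking. Returns the unrooted tree as a
# newick string plus the canonical keys of its internal splits.
nj_core <- function(D, labels) {
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  nwk <- labels
  sets <- as.list(labels)
  splits <- character(0)
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newset <- c(sets[[i]], sets[[j]])
    if (length(newset) >= 2L && length(newset) <= n - 2L)
      splits <- c(splits, canonical_split(newset, labels))
    newnwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], newnwk)
    sets <- c(sets[keep], list(newset))
    D <- D2
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", nwk[1], ":", fmt(l1), ",", nwk[2], ":", fmt(l2),
                   ",", nwk[3], ":", fmt(l3), ");")
  list(newick = newick, splits = unique(splits), labels = labels)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ (Saitou-Nei, Studier-Keppler Q-criterion) with deterministic
#' smallest-index tie-breaking; negative branch lengths are clamped to zero.
#'
#' @param d Symmetric labelled distance matrix (or `dist`).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  D <- as.matrix(d)
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  res <- nj_core(D, labels)
  ape::read.tree(text = res$newick)
}

# ---- Fitch machinery ---------------------------------------------------

FULL_MASK <- as.integer(sum(2^(0:19)))

# nsites x ntaxa integer bitmask encoding; gaps/ambiguity = all states.
encode_aa <- function(seqs) {
  m <- seq_matrix(seqs)
  idx <- match(m, AA_ALPHABET)
  enc <- ifelse(is.na(idx), FULL_MASK, as.integer(2^(idx - 1)))
  matrix(enc, nrow(m))   # rows = taxa
}

# Compile an edge-matrix topology into a postorder merge program rooted at
# leaf 1. Returns the program, each internal clade's leaf set, and canonical
# split keys (relative to integer leaf ids).
compile_topology <- function(edges, n) {
  adj <- vector("list", max(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  prog <- list(); sets <- list()
  slot <- n
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(list(slot = node, set = node))
    parts <- lapply(kids, rec, parent = node)
    s <- parts[[1]]$slot; set <- parts[[1]]$set
    for (k in seq_along(parts)[-1]) {
      slot <<- slot + 1L
      prog[[length(prog) + 1L]] <<- c(s, parts[[k]]$slot, slot)
      s <- slot
      set <- c(set, parts[[k]]$set)
    }
    sets[[length(sets) + 1L]] <<- sort(set)
    list(slot = s, set = sort(set))
  }
  root <- setdiff(adj[[1L]], integer(0))[1]   # leaf 1's neighbor
  top <- rec(root, 1L)
  # final union with leaf 1 closes the tree
  slot <- slot + 1L
  prog[[length(prog) + 1L]] <- c(top$slot, 1L, slot)
  keys <- vapply(sets[lengths(sets) >= 2 & lengths(sets) <= n - 2],
                 function(s) paste(s, collapse = "|"), "")
  list(prog = do.call(rbind, prog), n_slots = slot, n = n,
       sets = sets, splits = unique(keys))
}

# Per-site Fitch costs of a compiled topology.
fitch_site_costs <- function(ct, enc) {
  states <- vector("list", ct$n_slots)
  for (i in seq_len(ct$n)) states[[i]] <- enc[i, ]
  cost <- integer(ncol(enc))
  for (r in seq_len(nrow(ct$prog))) {
    a <- states[[ct$prog[r, 1]]]; b <- states[[ct$prog[r, 2]]]
    x <- bitwAnd(a, b)
    z <- x == 0L
    cost <- cost + z
    if (any(z)) x[z] <- bitwOr(a, b)[z]
    states[[ct$prog[r, 3]]] <- x
  }
  cost
}

fitch_length <- function(ct, enc, weights = NULL) {
  cost <- fitch_site_costs(ct, enc)
  if (is.null(weights)) sum(cost) else sum(cost * weights)
}

# Enumerate all unrooted binary topologies on n taxa (n <= 8; 10,395 at
# n = 8) by stepwise leaf insertion in a fixed, reproducible order.
.topo_cache <- new.env(parent = emptyenv())

enumerate_topologies <- function(n) {
  stopifnot(n >= 3L, n <= 8L)
  key <- as.character(n)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  res <- list()
  rec <- function(edges, next_node, k) {
    if (k > n) {
      res[[length(res) + 1L]] <<- edges
      return(invisible(NULL))
    }
    for (e in seq_len(nrow(edges))) {
      v <- next_node
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(edges[e, 1], v), c(v, edges[e, 2]), c(v, k))
      rec(new_edges, next_node + 1L, k + 1L)
    }
  }
  rec(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)), n + 2L, 4L)
  out <- lapply(res, compile_topology, n = n)
  .topo_cache[[key]] <- out
  out
}

# Matrix of per-site Fitch costs, one row per enumerated topology.
topology_cost_matrix <- function(topos, enc) {
  t(vapply(topos, fitch_site_costs, integer(ncol(enc)), enc = enc))
}

topology_newick <- function(edges, n, labels) {
  adj <- vector("list", max(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(labels[node])
    paste0("(", paste(vapply(kids, rec, "", parent = node), collapse = ","), ")")
  }
  root <- adj[[1L]][1]
  kids <- setdiff(adj[[root]], 1L)
  paste0("(", labels[1], ",",
         paste(vapply(kids, rec, "", parent = root), collapse = ","), ");")
}

# Branch and bound over leaf-insertion search space (used above 8 taxa).
bab_mp <- function(enc, n, labels) {
  best <- list(len = Inf, edges = NULL)
  rec <- function(edges, next_node, k) {
    ct <- compile_topology(edges, k - 1L)
    len <- fitch_length(ct, enc[seq_len(k - 1L), , drop = FALSE])
    if (len >= best$len) return(invisible(NULL))
    if (k > n) {
      best <<- list(len = len, edges = edges)
      return(invisible(NULL))
    }
    for (e in seq_len(nrow(edges))) {
      v <- next_node
      rec(rbind(edges[-e, , drop = FALSE],
                c(edges[e, 1], v), c(v, edges[e, 2]), c(v, k)),
          next_node + 1L, k + 1L)
    }
  }
  # leaf insertion needs internal ids that never collide with leaf ids
  rec(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)), n + 2L, 4L)
  best
}

#' Exact maximum-parsimony tree
#'
#' Minimizes the Fitch parsimony length over all unrooted binary topologies:
#' by exhaustive enumeration up to 8 taxa, by branch and bound (with the
#' current Fitch length of the partial tree as lower bound) up to
#' `max_taxa`. The search order is fixed, so ties resolve deterministically
#' to the first optimal topology in enumeration order.
#'
#' @param seqs Named character vector of aligned amino-acid strings.
#' @param max_taxa Hard limit (default 12); beyond it the exact search is
#'   refused with advice to use the NJ-based methods.
#' @return A `phylo` tree (no branch lengths) with attribute `pscore`, the
#'   minimum Fitch length.
#' @export
max_parsimony <- function(seqs, max_taxa = 12) {
  n <- length(seqs)
  labels <- names(seqs) %||% paste0("t", seq_len(n))
  if (n < 3L) stop("maximum parsimony needs at least 3 taxa")
  if (n > max_taxa)
    stop("too many taxa for exact parsimony search (", n, " > ", max_taxa,
         "); use the NJ-only mode")
  enc <- encode_aa(seqs)
  if (n == 3L) {
    edges <- rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L))
    len <- fitch_length(compile_topology(edges, 3L), enc)
    tr <- ape::read.tree(text = topology_newick(edges, 3L, labels))
    attr(tr, "pscore") <- len
    return(tr)
  }
  if (n <= 8L) {
    topos <- enumerate_topologies(n)
    lens <- as.vector(topology_cost_matrix(topos, enc) %*%
                        rep(1, ncol(enc)))
    idx <- which.min(lens)
    # recover edge matrix by re-running the enumeration order
    edges <- enumeration_edges(n)[[idx]]
    tr <- ape::read.tree(text = topology_newick(edges, n, labels))
    attr(tr, "pscore") <- lens[idx]
    return(tr)
  }
  best <- bab_mp(enc, n, labels)
  tr <- ape::read.tree(text = topology_newick(best$edges, n, labels))
  attr(tr, "pscore") <- best$len
  tr
}

# Raw edge matrices in the same order as enumerate_topologies().
enumeration_edges <- function(n) {
  key <- paste0("edges", n)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  res <- list()
  rec <- function(edges, next_node, k) {
    if (k > n) { res[[length(res) + 1L]] <<- edges; return(invisible(NULL)) }
    for (e in seq_len(nrow(edges))) {
      v <- next_node
      rec(rbind(edges[-e, , drop = FALSE],
                c(edges[e, 1], v), c(v, edges[e, 2]), c(v, k)),
          next_node + 1L, k + 1L)
    }
  }
  rec(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)), n + 2L, 4L)
  .topo_cache[[key]] <- res
  res
}

#' Fitch parsimony length of a given tree
#'
#' @param tree A `phylo` tree whose tips match `names(seqs)`.
#' @param seqs Named character vector of aligned amino-acid strings.
#' @return Integer parsimony length.
#' @export
parsimony_length <- function(tree, seqs) {
  ord <- match(tree$tip.label, names(seqs))
  if (anyNA(ord)) stop("tree tips and sequence names do not match")
  enc <- encode_aa(seqs)[ord, , drop = FALSE]
  nt <- length(tree$tip.label)
  edges <- tree$edge
  # treat the phylo as an unrooted adjacency and reuse the compiler
  ct <- compile_topology(edges, nt)
  fitch_length(ct, enc)
}

# ---- splits and support -------------------------------------------------

# Leaf-name sets of every internal node of a phylo (rooted as stored).
phylo_clades <- function(tree) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  res <- vector("list", tree$Nnode)
  rec <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    tips <- unlist(lapply(kids[[as.character(node)]], rec))
    res[[node - nt]] <<- tips
    tips
  }
  rec(nt + 1L)
  res
}

splits_of_phylo <- function(tree) {
  labels <- sort(tree$tip.label)
  cl <- phylo_clades(tree)
  keys <- vapply(cl, function(s) {
    if (length(s) < 2 || length(s) > length(labels) - 2) return(NA_character_)
    canonical_split(s, labels)
  }, "")
  unique(keys[!is.na(keys)])
}

#' Bootstrap support for a tree method
#'
#' Builds the reference tree with the requested method, then resamples
#' alignment columns with replacement `replicates` times, rebuilds, and
#' reports for every internal edge of the reference tree the percentage of
#' replicate trees containing the same bipartition. Reproducible for a fixed
#' seed.
#'
#' @param seqs Named character vector of aligned amino-acid strings.
#' @param builder `"nj"` (step-matrix distances), `"mp"` (exact parsimony)
#'   or `"ml"` (NJ over JTT maximum-likelihood distances, the ML-surrogate).
#' @param replicates Bootstrap replicates (survey defaults: 1,000 for NJ,
#'   100 for MP).
#' @param seed Integer seed for the column resampling.
#' @param cost Step matrix for `builder = "nj"`.
#' @return List with `tree` (reference `phylo`, `node.label` = integer
#'   support), `support` (named vector, canonical split key -> percentage),
#'   `builder`, `replicates`, `seed`.
#' @export
bootstrap_support <- function(seqs, builder = c("nj", "mp", "ml"),
                              replicates = 1000, seed = 1,
                              cost = step_matrix_pam250()) {
  builder <- match.arg(builder)
  stopifnot(replicates >= 1)
  n <- length(seqs)
  labels <- names(seqs)
  L <- nchar(seqs[[1]])
  sorted_labels <- sort(labels)
  enc <- if (builder == "mp") encode_aa(seqs)
  relabel <- function(keys_int) {
    # integer-id keys (taxon order) -> canonical name keys
    vapply(strsplit(keys_int, "|", fixed = TRUE), function(s)
      canonical_split(labels[as.integer(s)], sorted_labels), "")
  }
  topos <- NULL; Cmat <- NULL; pc <- NULL
  if (builder == "mp" && n <= 8L) {
    topos <- enumerate_topologies(n)
    Cmat <- topology_cost_matrix(topos, enc)
  }
  if (builder == "nj") pc <- pair_site_costs(seqs, cost)
  build_ref <- function() {
    switch(builder,
      nj = {
        res <- nj_core(pairwise_distances(seqs, cost), labels)
        list(tree = ape::read.tree(text = res$newick),
             splits = vapply(strsplit(res$splits, "|", fixed = TRUE),
                             function(s) canonical_split(s, sorted_labels), ""))
      },
      ml = {
        res <- nj_core(dist_ml_jtt(seqs), labels)
        list(tree = ape::read.tree(text = res$newick),
             splits = vapply(strsplit(res$splits, "|", fixed = TRUE),
                             function(s) canonical_split(s, sorted_labels), ""))
      },
      mp = {
        tr <- max_parsimony(seqs)
        list(tree = tr, splits = splits_of_phylo(tr))
      })
  }
  ref <- build_ref()
  counts <- stats::setNames(numeric(length(ref$splits)), ref$splits)
  m_chars <- if (builder == "ml") {
    mm <- seq_matrix(seqs)
    mm[!(mm %in% c(AA_ALPHABET, "B", "Z", "X", "-", "?"))] <- "X"
    mm
  }
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      keys <- switch(builder,
        nj = {
          w <- tabulate(idx, nbins = L)
          D <- pair_dist_from_weights(pc, w)
          if (anyNA(D)) next
          rel <- nj_core(D, labels)$splits
          vapply(strsplit(rel, "|", fixed = TRUE),
                 function(s) canonical_split(s, sorted_labels), "")
        },
        ml = {
          mm <- m_chars[, idx, drop = FALSE]
          rownames(mm) <- labels
          D <- as.matrix(phangorn::dist.ml(phangorn::phyDat(mm, type = "AA"),
                                           model = "JTT"))
          rel <- nj_core(D, labels)$splits
          vapply(strsplit(rel, "|", fixed = TRUE),
                 function(s) canonical_split(s, sorted_labels), "")
        },
        mp = {
          if (!is.null(Cmat)) {
            w <- tabulate(idx, nbins = L)
            top <- which.min(as.vector(Cmat %*% w))
            relabel(topos[[top]]$splits)
          } else {
            tr <- max_parsimony(lapply(seqs, function(s)
              paste(split_chars(s)[idx], collapse = "")) |>
                unlist() |> stats::setNames(labels))
            splits_of_phylo(tr)
          }
        })
      hit <- names(counts) %in% keys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / replicates)
  tree <- ref$tree
  cl <- phylo_clades(tree)
  nl <- vapply(cl, function(s) {
    if (length(s) < 2 || length(s) > n - 2) return(NA_real_)
    unname(support[canonical_split(s, sorted_labels)])
  }, 0)
  tree$node.label <- ifelse(is.na(nl), "", as.character(as.integer(nl)))
  list(tree = tree, support = support, builder = builder,
       replicates = replicates, seed = seed)
}

#' Monophyly test on a tree rooted by an outgroup
#'
#' Roots the tree on the outgroup and reports whether some clade's leaf set
#' equals `taxa` exactly.
#'
#' @param tree A `phylo` tree containing the outgroup leaf.
#' @param taxa Character vector of tip labels.
#' @param outgroup Outgroup tip label used for rooting.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("taxa not in tree: ", paste(miss, collapse = ", "))
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  cl <- phylo_clades(rt)
  any(vapply(cl, function(s) setequal(s, taxa), TRUE))
}
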