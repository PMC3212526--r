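# Translated six-frame motif scanning with intron-aware segment chaining.
# Replaces the tblastn stage of the original survey: each reference motif is
# aligned locally against all six translation frames, sub-hits on the same
# strand are chained across intron-sized gaps, missing exons are rescued by
# targeted re-search of the gap windows, and exon boundaries are refined
# against GT..AG splice signals.

#' Scan configuration
#'
#' @param score_threshold Minimum score (substitution-matrix units) for a
#'   reported hit. The default is deliberately permissive, mirroring the
#'   E = 10 search contract of the original survey.
#' @param piece_threshold Minimum local-alignment score for a sub-hit to
#'   enter chaining.
#' @param rescue_threshold Minimum score for a sub-hit recovered by targeted
#'   re-search of a chain gap (the emulation of manually completing
#'   intron-interrupted hits).
#' @param max_gap_bp Maximum genomic gap bridged between chained sub-hits
#'   (default 50 kb, covering the longest observed motif intron of 45,217 bp).
#' @param substitution_matrix Name of the amino-acid scoring matrix.
#' @param gap_opening,gap_extension Alignment gap penalties.
#' @param max_pieces Maximum sub-hits extracted per query and frame by
#'   iterative masking (beyond the first, batched pass).
#' @param refine Refine chained exon boundaries against GT..AG splice
#'   dinucleotides, extend terminal exons to full query coverage, and drop
#'   terminal segments whose junction shows no splice signal.
#' @param min_intron Minimum genomic gap treated as an intron during
#'   refinement (bp).
#' @param junction_penalty Score charged per chain junction, so weak sub-hits
#'   cannot buy their way into a chain (genuine weak exons are recovered by
#'   the gap rescue instead, which validates placements against splice
#'   signals).
#' @return A `scan_config` list.
#' @export
scan_config <- function(score_threshold = 30, piece_threshold = 28,
                        rescue_threshold = 12, max_gap_bp = 50000,
                        substitution_matrix = "BLOSUM62",
                        gap_opening = 25, gap_extension = 5, max_pieces = 2,
                        refine = TRUE, min_intron = 30,
                        junction_penalty = 35) {
  stopifnot(is.finite(score_threshold), max_gap_bp >= 0)
  structure(list(score_threshold = score_threshold,
                 piece_threshold = piece_threshold,
                 rescue_threshold = rescue_threshold,
                 max_gap_bp = max_gap_bp,
                 substitution_matrix = substitution_matrix,
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 max_pieces = max_pieces, refine = refine,
                 min_intron = min_intron,
                 junction_penalty = junction_penalty),
            class = "scan_config")
}

validate_dna <- function(s) {
  bad <- regexpr("[^ACGTURYSWKMBDHVN]", toupper(s))
  if (bad > 0)
    stop("non-IUPAC nucleotide character '", substring(s, bad, bad),
         "' at position ", bad)
  invisible(s)
}

# Codon lookup built once from the standard genetic code; codons holding
# ambiguity characters translate as X (and never count as matches).
.trans_env <- new.env(parent = emptyenv())

codon_table_lookup <- function() {
  if (is.null(.trans_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .trans_env$tab <- stats::setNames(unname(gc), names(gc))
  }
  .trans_env$tab
}

translate_frame <- function(dna, offset) {
  n <- nchar(dna)
  len <- ((n - offset + 1L) %/% 3L) * 3L
  if (len < 3L) return("")
  s <- substring(dna, offset, offset + len - 1L)
  starts <- seq.int(1L, len, 3L)
  aa <- codon_table_lookup()[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

score_matrix <- function(name) {
  # substitution matrices shipped with Biostrings (BLOSUM*, PAM*)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# Positional (ungapped) score of two equal-length amino-acid strings.
positional_score <- function(a, b, mat) {
  ca <- split_chars(a); cb <- split_chars(b)
  keep <- ca %in% rownames(mat) & cb %in% colnames(mat)
  sum(mat[cbind(ca[keep], cb[keep])])
}

local_align <- function(query, subject, cfg, mat) {
  Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = mat,
    gapOpening = cfg$gap_opening, gapExtension = cfg$gap_extension)
}

piece_row <- function(pa, i = 1L) {
  data.frame(q_start = Biostrings::start(Biostrings::pattern(pa))[i],
             q_end = Biostrings::end(Biostrings::pattern(pa))[i],
             s_start = Biostrings::start(Biostrings::subject(pa))[i],
             s_end = Biostrings::end(Biostrings::subject(pa))[i],
             score = Biostrings::score(pa)[i],
             has_gap = grepl("-", as.character(Biostrings::pattern(pa))[i],
                             fixed = TRUE) ||
               grepl("-", as.character(Biostrings::subject(pa))[i],
                     fixed = TRUE))
}

# All sub-hits of all queries against one translated frame: one batched
# local-alignment pass, then per-query masked re-alignment for further
# same-frame exons.
frame_pieces <- function(prot, qset, cfg, mat) {
  out <- rep(list(NULL), length(qset))
  if (nchar(prot) < 5L) return(out)
  pa <- local_align(qset, Biostrings::AAString(prot), cfg, mat)
  scs <- Biostrings::score(pa)
  for (qi in which(scs >= cfg$piece_threshold)) {
    ps <- list(piece_row(pa, qi))
    if (cfg$max_pieces > 1L) {
      subj <- prot
      for (k in seq_len(cfg$max_pieces - 1L)) {
        last <- ps[[length(ps)]]
        substring(subj, last$s_start, last$s_end) <-
          strrep("X", last$s_end - last$s_start + 1L)
        pa1 <- local_align(qset[qi], Biostrings::AAString(subj), cfg, mat)
        if (Biostrings::score(pa1) < cfg$piece_threshold) break
        ps[[length(ps) + 1L]] <- piece_row(pa1)
      }
    }
    out[[qi]] <- do.call(rbind, ps)
  }
  out
}

# Trim a gapless sub-hit to its high-confidence core: terminal residues up
# to the first strongly matching position are dropped (local alignments
# over-extend into intron translation on chance matches; the splice-signal
# refinement re-extends boundaries precisely). Sub-hits with no core are
# noise and are discarded.
trim_piece_core <- function(p, query, coding, mat, min_core = 3L, floor = 4) {
  if (isTRUE(p$has_gap)) return(p)
  len <- p$q_end - p$q_start + 1L
  qres <- split_chars(substring(query, p$q_start, p$q_end))
  pres <- split_chars(translate_frame(substring(coding, p$c_start, p$c_end), 1L))
  if (length(pres) != len) return(p)
  s <- mat[cbind(pres, qres)]
  s[is.na(s)] <- -2
  l <- which(s >= floor)[1]
  r <- rev(which(s >= floor))[1]
  if (is.na(l) || r - l + 1L < min_core) return(NULL)
  # additionally require a solid terminal window: a single chance match is
  # not enough to anchor a piece end inside intron translation
  while (r - l + 1L > min_core + 2L && s[l] + s[l + 1L] + s[l + 2L] < 6) l <- l + 1L
  while (r - l + 1L > min_core + 2L && s[r] + s[r - 1L] + s[r - 2L] < 6) r <- r - 1L
  while (l < r && s[l] < floor) l <- l + 1L
  while (r > l && s[r] < floor) r <- r - 1L
  if (r - l + 1L < min_core) return(NULL)
  p$q_start <- p$q_start + l - 1L
  p$q_end <- p$q_end - (len - r)
  p$c_start <- p$c_start + 3L * (l - 1L)
  p$c_end <- p$c_end - 3L * (len - r)
  p$score <- sum(s[l:r])
  p
}

# Best-scoring compatible chain of sub-hits (coding-strand coordinates).
chain_pieces <- function(p, cfg) {
  p <- p[order(p$q_start, p$c_start), , drop = FALSE]
  n <- nrow(p)
  best <- p$score; prev <- rep(NA_integer_, n)
  # local alignments may over-extend past the true exon boundary into
  # intron translation; allow sizeable query overlaps and trim them during
  # refinement
  qo <- 12L
  J <- cfg$junction_penalty %||% 0
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    gap <- p$c_start[i] - p$c_end[j] - 1L
    if (p$q_start[i] > p$q_end[j] - qo && p$q_end[i] > p$q_end[j] &&
        gap >= 0L && gap <= cfg$max_gap_bp &&
        best[j] + p$score[i] - J > best[i]) {
      best[i] <- best[j] + p$score[i] - J
      prev[i] <- j
    }
  }
  i <- which.max(best)
  idx <- i
  while (!is.na(prev[i])) { i <- prev[i]; idx <- c(i, idx) }
  list(rows = p[idx, , drop = FALSE], score = max(best), used = idx, all = p)
}

# Ungapped positional scan: slide a query stretch along all three frames
# of a genomic window and return the best-scoring placements.
scan_gap_exon <- function(sub_q, window, mat, top = 5L) {
  M <- nchar(sub_q)
  qres <- split_chars(sub_q)
  cands <- list()
  for (f in 1:3) {
    prot <- translate_frame(window, f)
    W <- nchar(prot)
    if (W < M) next
    pres <- split_chars(prot)
    total <- numeric(W - M + 1L)
    for (i in seq_len(M)) {
      v <- mat[cbind(pres[i:(W - M + i)], qres[i])]
      v[is.na(v)] <- -2
      total <- total + v
    }
    ord <- order(-total)[seq_len(min(top, length(total)))]
    for (o in ord)
      cands[[length(cands) + 1L]] <-
        list(score = total[o], start_in_window = f + 3L * (o - 1L))
  }
  cands[order(-vapply(cands, `[[`, 0, "score"))]
}

# Targeted re-search of chain gaps: when chained sub-hits leave part of the
# query uncovered (a weak or same-frame exon the first pass missed), place
# the exactly-missing residue stretch by positional scan of the gap window,
# preferring placements flanked by splice signals (the emulation of
# manually completing intron-interrupted hits). Iterates until no gap can
# be filled.
rescue_chain <- function(rows, query, coding, cfg, mat) {
  qlen <- nchar(query); clen <- nchar(coding)
  for (iter in 1:6) {
    gaps <- list()
    if (rows$q_start[1] >= 5L)
      gaps[[length(gaps) + 1L]] <-
        list(qa = 1L, qb = rows$q_start[1] - 1L,
             ca = max(1L, rows$c_start[1] - cfg$max_gap_bp),
             cb = rows$c_start[1] - 1L, kind = "lead")
    k <- nrow(rows)
    if (rows$q_end[k] <= qlen - 4L)
      gaps[[length(gaps) + 1L]] <-
        list(qa = rows$q_end[k] + 1L, qb = qlen,
             ca = rows$c_end[k] + 1L,
             cb = min(clen, rows$c_end[k] + cfg$max_gap_bp), kind = "trail")
    if (k > 1L) for (i in seq_len(k - 1L)) {
      if (rows$q_start[i + 1L] - rows$q_end[i] - 1L >= 3L)
        gaps[[length(gaps) + 1L]] <-
          list(qa = rows$q_end[i] + 1L, qb = rows$q_start[i + 1L] - 1L,
               ca = rows$c_end[i] + 1L, cb = rows$c_start[i + 1L] - 1L,
               kind = "internal", row = i)
    }
    added <- FALSE
    for (gp in gaps) {
      M <- gp$qb - gp$qa + 1L
      if (M < 2L || gp$cb - gp$ca + 1L < 3L * M + 6L) next
      if (gp$kind == "internal") {
        # split fill: the missing block may simply straddle one splice
        # junction, its prefix continuing the upstream exon and its suffix
        # opening the downstream one -- both ends are pinned by the cores,
        # only the split point is free
        i <- gp$row
        ce <- rows$c_end[i]; cs <- rows$c_start[i + 1L]
        best_fill <- NULL
        for (j in gp$qa:(gp$qb + 1L)) {
          pe <- ce + 3L * (j - gp$qa)
          ss <- cs - 3L * (gp$qb - j + 1L)
          if (ss - pe - 1L < max(4L, cfg$min_intron)) next
          if (substring(coding, pe + 1L, pe + 2L) != "GT" ||
              substring(coding, ss - 2L, ss - 1L) != "AG") next
          sc <- 0
          if (j > gp$qa)
            sc <- sc + positional_score(
              translate_frame(substring(coding, ce + 1L, pe), 1L),
              substring(query, gp$qa, j - 1L), mat)
          if (j <= gp$qb)
            sc <- sc + positional_score(
              translate_frame(substring(coding, ss, cs - 1L), 1L),
              substring(query, j, gp$qb), mat)
          if (is.null(best_fill) || sc > best_fill$sc)
            best_fill <- list(j = j, pe = pe, ss = ss, sc = sc)
        }
        if (!is.null(best_fill) && best_fill$sc >= 2 * M) {
          rows$c_end[i] <- best_fill$pe
          rows$q_end[i] <- best_fill$j - 1L
          rows$c_start[i + 1L] <- best_fill$ss
          rows$q_start[i + 1L] <- best_fill$j
          added <- TRUE
          break
        }
      }
      # the block may hold whole missing exons plus a few residues that
      # really belong to the flanking exons (trimmed boundary overhangs).
      # Place the best-supported sub-block: the offset d1 from the upstream
      # side is small when that side adjoins an exon core, and the residues
      # left over on an open (terminal) side may be a further exon, reached
      # by the next rescue pass. All sub-block lengths are scored in one
      # cumulative pass per offset.
      win <- substring(coding, gp$ca, gp$cb)
      d1_cap <- if (gp$kind == "lead") min(10L, M - 3L) else min(6L, M - 3L)
      best <- NULL
      for (d1 in 0:d1_cap) {
        M1 <- M - d1
        if (M1 < 3L) break
        qres <- split_chars(substring(query, gp$qa + d1, gp$qb))
        for (f in 1:3) {
          prot <- translate_frame(win, f)
          W <- nchar(prot)
          if (W < 3L) next
          pres <- split_chars(prot)
          total <- numeric(W)
          for (i in seq_len(min(M1, W))) {
            v <- mat[cbind(pres[i:W], qres[i])]
            v[is.na(v)] <- -2
            total <- total + c(v, rep(-1e6, i - 1L))
            if (i < 3L) next
            d2 <- M1 - i
            if (d2 > 0L && gp$kind != "trail" && d2 > 6L) next
            tt <- total
            for (k in 1:3) {
              o <- which.max(tt)
              sc <- tt[o]
              if (sc < max(cfg$rescue_threshold, 1.5 * i)) break
              cs <- gp$ca - 1L + f + 3L * (o - 1L)
              ce <- cs + 3L * i - 1L
              if (ce <= gp$cb) {
                left_ok <- (gp$kind == "lead" && d1 == 0L) ||
                  substring(coding, cs - 2L, cs - 1L) == "AG"
                right_ok <- (gp$kind == "trail" && d2 == 0L) ||
                  substring(coding, ce + 1L, ce + 2L) == "GT"
                score_adj <- sc - 2 * (d1 + d2)
                if (left_ok && right_ok &&
                    (is.null(best) || score_adj > best$score_adj))
                  best <- list(score = sc, score_adj = score_adj,
                               cs = cs, ce = ce, d1 = d1, d2 = d2)
              }
              tt[o] <- -Inf
            }
          }
        }
      }
      if (is.null(best)) next
      newrow <- data.frame(
        q_start = gp$qa + best$d1, q_end = gp$qb - best$d2,
        s_start = NA_integer_, s_end = NA_integer_, score = best$score,
        has_gap = FALSE, c_start = best$cs, c_end = best$ce)
      # placement is already validated (exact length, inside the gap, splice
      # flanks); insert it directly rather than re-running the chain DP
      rows <- rbind(rows, newrow)
      rows <- rows[order(rows$q_start), , drop = FALSE]
      added <- TRUE
      break
    }
    if (!added) break
  }
  rows
}

# Adjust chained exon boundaries: extend terminal exons to full query
# coverage and place each internal boundary so the intron carries GT..AG
# terminal dinucleotides (emulating the manual splice curation of the
# original survey). Junctions whose gap is too wide for a boundary shift
# are left untouched; terminal pieces whose junction shows no splice
# signal are dropped as chaining artifacts.
refine_chain <- function(rows, query, coding, cfg, mat) {
  qlen <- nchar(query); clen <- nchar(coding)
  gapless <- (rows$c_end - rows$c_start + 1L) ==
    3L * (rows$q_end - rows$q_start + 1L)
  if (!is.null(rows$has_gap)) gapless <- gapless & !rows$has_gap
  k <- nrow(rows)
  if (gapless[1]) {
    ext <- min(rows$q_start[1] - 1L, (rows$c_start[1] - 1L) %/% 3L)
    rows$c_start[1] <- rows$c_start[1] - 3L * ext
    rows$q_start[1] <- rows$q_start[1] - ext
  }
  if (gapless[k]) {
    ext <- min(qlen - rows$q_end[k], (clen - rows$c_end[k]) %/% 3L)
    rows$c_end[k] <- rows$c_end[k] + 3L * ext
    rows$q_end[k] <- rows$q_end[k] + ext
  }
  splice_ok <- rep(TRUE, max(k - 1L, 0L))
  if (k > 1L) for (i in seq_len(k - 1L)) {
    if (!gapless[i] || !gapless[i + 1L]) next
    if (rows$q_start[i + 1L] - rows$q_end[i] - 1L > 6L) {
      splice_ok[i] <- FALSE      # unfilled gap: leave boundaries alone
      next
    }
    lo <- max(rows$q_start[i], rows$q_end[i] - 12L)
    hi <- min(rows$q_end[i + 1L] - 1L, rows$q_start[i + 1L] + 12L)
    ok <- integer(0)
    for (cc in if (lo <= hi) lo:hi else integer(0)) {
      e2 <- rows$c_end[i] + 3L * (cc - rows$q_end[i])
      s2 <- rows$c_start[i + 1L] - 3L * (rows$q_start[i + 1L] - 1L - cc)
      if (e2 < rows$c_start[i] + 2L || s2 > rows$c_end[i + 1L] - 2L) next
      if (s2 - e2 - 1L < max(4L, cfg$min_intron)) next
      if (substring(coding, e2 + 1L, e2 + 2L) == "GT" &&
          substring(coding, s2 - 2L, s2 - 1L) == "AG") ok <- c(ok, cc)
    }
    cc <- if (length(ok) == 0L) {
      splice_ok[i] <- FALSE
      min(rows$q_end[i], rows$q_start[i + 1L] - 1L)
    } else if (length(ok) == 1L) ok else {
      # several GT..AG-compatible splits: keep the best-scoring translation
      sc <- vapply(ok, function(cc) {
        e2 <- rows$c_end[i] + 3L * (cc - rows$q_end[i])
        s2 <- rows$c_start[i + 1L] - 3L * (rows$q_start[i + 1L] - 1L - cc)
        sp <- paste0(substring(coding, rows$c_start[i], e2),
                     substring(coding, s2, rows$c_end[i + 1L]))
        positional_score(translate_frame(sp, 1L),
                         substring(query, rows$q_start[i],
                                   rows$q_end[i + 1L]), mat)
      }, 0)
      ok[which.max(sc)]
    }
    rows$c_end[i] <- rows$c_end[i] + 3L * (cc - rows$q_end[i])
    rows$q_end[i] <- cc
    rows$c_start[i + 1L] <- rows$c_start[i + 1L] -
      3L * (rows$q_start[i + 1L] - 1L - cc)
    rows$q_start[i + 1L] <- cc + 1L
  }
  # drop terminal chaining artifacts (no splice signal at the junction)
  while (nrow(rows) > 1L && !splice_ok[length(splice_ok)]) {
    rows <- rows[-nrow(rows), , drop = FALSE]
    splice_ok <- splice_ok[-length(splice_ok)]
  }
  while (nrow(rows) > 1L && !splice_ok[1]) {
    rows <- rows[-1L, , drop = FALSE]
    splice_ok <- splice_ok[-1L]
  }
  rows
}

hit_record <- function(rows, contig_id, strand, clen, query_id, coding,
                       cfg, mat, query) {
  spliced <- paste(substring(coding, rows$c_start, rows$c_end), collapse = "")
  spliced <- substring(spliced, 1L, (nchar(spliced) %/% 3L) * 3L)
  translated <- if (nchar(spliced) >= 3L) translate_frame(spliced, 1L) else ""
  score <- if (nchar(translated) == nchar(query))
    positional_score(translated, query, mat)
  else if (nchar(translated) >= 3L)
    Biostrings::score(local_align(Biostrings::AAString(query),
                                  Biostrings::AAString(translated), cfg, mat))
  else -Inf
  if (strand == "+") { g_start <- rows$c_start; g_end <- rows$c_end }
  else { g_start <- clen - rows$c_start + 1L; g_end <- clen - rows$c_end + 1L }
  segs <- data.frame(start = g_start, end = g_end,
                     frame = vapply(g_start, segment_frame, "",
                                    strand = strand, contig_len = clen),
                     stringsAsFactors = FALSE)
  data.frame(contig = contig_id, frame = segs$frame[1], strand = strand,
             score = score, query_id = query_id, translated_seq = translated,
             n_segments = nrow(segs),
             span_lo = min(g_start, g_end), span_hi = max(g_start, g_end),
             segments = I(list(segs)), stringsAsFactors = FALSE)
}

#' Six-frame translated scan of a contig for bHLH motifs
#'
#' Every query motif is locally aligned against all six translation frames
#' (one batched pass per frame); sub-hits on the same strand within
#' `max_gap_bp` are chained into one multi-segment (intron-interrupted)
#' candidate hit, chain gaps are re-searched for missed exons, and exon
#' boundaries are refined against GT..AG splice signals. Segment
#' coordinates are 1-based inclusive; minus-strand segments are recorded in
#' descending (reading) order, matching the published table conventions.
#'
#' @param contig Nucleotide string (IUPAC; ambiguity codes translate as X).
#' @param queries A `bhlh_refset` (or data frame with `id`, `sequence`).
#' @param cfg A [scan_config()].
#' @param contig_id Label recorded in the hits.
#' @return Data frame of candidate hits (columns `contig`, `frame`,
#'   `strand`, `score`, `query_id`, `translated_seq`, `n_segments`,
#'   `span_lo`, `span_hi`, and list-column `segments`).
#' @export
six_frame_scan <- function(contig, queries, cfg = scan_config(),
                           contig_id = "contig") {
  contig <- toupper(as.character(contig))
  if (nchar(contig) < 3L) stop("contig shorter than one codon")
  if (!nrow(queries)) stop("no query motifs supplied")
  validate_dna(contig)
  mat <- score_matrix(cfg$substitution_matrix)
  clen <- nchar(contig)
  qset <- Biostrings::AAStringSet(queries$sequence)
  hits <- list()
  for (strand in c("+", "-")) {
    coding <- if (strand == "+") contig else revcomp(contig)
    prots <- lapply(1:3, function(f) translate_frame(coding, f))
    by_frame <- lapply(prots, frame_pieces, qset = qset, cfg = cfg, mat = mat)
    chains <- vector("list", nrow(queries))
    for (qi in seq_len(nrow(queries))) {
      pieces <- list()
      for (f in 1:3) {
        p <- by_frame[[f]][[qi]]
        if (is.null(p)) next
        p$c_start <- f + 3L * (p$s_start - 1L)
        p$c_end <- f + 3L * p$s_end - 1L
        pieces[[length(pieces) + 1L]] <- p
      }
      if (length(pieces)) {
        p <- do.call(rbind, pieces)
        query <- queries$sequence[qi]
        cores <- lapply(seq_len(nrow(p)), function(r)
          trim_piece_core(p[r, , drop = FALSE], query, coding, mat))
        p <- do.call(rbind, cores[!vapply(cores, is.null, TRUE)])
        if (!is.null(p) && nrow(p))
          chains[[qi]] <- chain_pieces(p, cfg)
      }
    }
    # gap rescue involves re-aligning against long genomic windows; spend
    # it only on chains competitive at their locus (dedup keeps the best
    # hit per locus anyway)
    best_strand <- max(c(0, vapply(chains, function(ch)
      if (is.null(ch)) 0 else ch$score, 0)))
    for (qi in seq_len(nrow(queries))) {
      ch <- chains[[qi]]
      if (is.null(ch)) next
      query <- queries$sequence[qi]
      rows <- ch$rows
      if (cfg$refine && ch$score >= max(45, 0.75 * best_strand)) {
        rows <- rescue_chain(rows, query, coding, cfg, mat)
        rows <- refine_chain(rows, query, coding, cfg, mat)
      }
      rec <- hit_record(rows, contig_id, strand, clen, queries$id[qi],
                        coding, cfg, mat, query)
      if (rec$score >= cfg$score_threshold)
        hits[[length(hits) + 1L]] <- rec
      # leftover sub-hits strong enough to stand alone (other loci)
      left <- ch$all[-ch$used, , drop = FALSE]
      left <- left[left$score >= cfg$score_threshold, , drop = FALSE]
      for (i in seq_len(nrow(left)))
        hits[[length(hits) + 1L]] <-
          hit_record(left[i, ], contig_id, strand, clen, queries$id[qi],
                     coding, cfg, mat, query)
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$span_lo, out$frame, out$query_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(contig = character(), frame = character(), strand = character(),
             score = numeric(), query_id = character(),
             translated_seq = character(), n_segments = integer(),
             span_lo = integer(), span_hi = integer(),
             segments = I(list()), stringsAsFactors = FALSE)
}

#' Scan a whole genome (set of contigs)
#'
#' @param contigs Named character vector (or `DNAStringSet`) of contigs.
#' @param queries,cfg As in [six_frame_scan()].
#' @return Combined hit table sorted by contig and leftmost coordinate.
#' @export
scan_genome <- function(contigs, queries, cfg = scan_config()) {
  nm <- names(contigs)
  contigs <- as.character(contigs)
  names(contigs) <- nm %||% paste0("contig", seq_along(contigs))
  res <- lapply(names(contigs), function(id)
    six_frame_scan(contigs[[id]], queries, cfg, contig_id = id))
  out <- do.call(rbind, res)
  out[order(out$contig, out$span_lo), , drop = FALSE]
}

#' Deduplicate candidate hits
#'
#' Among hits sharing contig, reading frame and overlapping coding regions,
#' only the highest-scoring survives (the survey's rule of keeping one
#' sequence per contig/frame/coding-region combination). Idempotent and
#' order-independent; output sorted by contig and leftmost coordinate.
#'
#' @param hits Hit table as returned by [six_frame_scan()].
#' @return Deduplicated hit table.
#' @export
dedupe_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$contig, hits$frame, hits$span_lo, -hits$score,
                     hits$query_id), , drop = FALSE]
  keep <- logical(nrow(hits))
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$contig, hits$frame, sep = "\r"))
  for (idx in groups) {
    # sweep: transitive overlap clusters within one contig+frame
    cl_end <- -Inf; cl_rows <- integer(0)
    flush <- function(rows) {
      if (!length(rows)) return()
      best <- rows[order(-hits$score[rows], hits$span_lo[rows],
                         hits$query_id[rows])][1]
      keep[best] <<- TRUE
    }
    for (i in idx) {
      if (hits$span_lo[i] > cl_end) {
        flush(cl_rows); cl_rows <- integer(0); cl_end <- -Inf
      }
      cl_rows <- c(cl_rows, i)
      cl_end <- max(cl_end, hits$span_hi[i])
    }
    flush(cl_rows)
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$contig, out$span_lo), , drop = FALSE]
}

#' Serialize hits to a flat TSV-ready table
#'
#' Segments are flattened to `start-end` strings joined by `;`, mirroring
#' the published table's "coding region(s)" column.
#'
#' @param hits Hit table.
#' @return Plain data frame with no list columns.
#' @export
hits_table <- function(hits) {
  seg <- vapply(hits$segments, function(s)
    paste(paste0(s$start, "-", s$end), collapse = ";"), "")
  frames <- vapply(hits$segments, function(s) paste(s$frame, collapse = ";"), "")
  data.frame(contig = hits$contig, frame = frames, coding_regions = seg,
             score = hits$score, query_id = hits$query_id,
             translated_seq = hits$translated_seq, stringsAsFactors = FALSE)
}

#' Two-stage genome scan with per-family query refinement
#'
#' Stage 1 scans with one representative motif per family; for each contig
#' the families of the strongest hits are then re-scanned with their full
#' membership, so the closest available relative of every locus also serves
#' as a query (the published surveys used every reference motif as a query;
#' this keeps that property at a fraction of the cost). Results of both
#' stages are pooled; deduplicate with [dedupe_hits()].
#'
#' @param contigs Named character vector (or `DNAStringSet`) of contigs.
#' @param refset Reference set list (`refs` etc.).
#' @param cfg A [scan_config()].
#' @param top_families Families re-scanned in full per contig (default 2).
#' @return Combined hit table.
#' @export
scan_genome_members <- function(contigs, refset, cfg = scan_config(),
                                top_families = 2) {
  nm <- names(contigs)
  contigs <- as.character(contigs)
  names(contigs) <- nm %||% paste0("contig", seq_along(contigs))
  reps <- refset$refs[!duplicated(refset$refs$family), , drop = FALSE]
  out <- list()
  for (id in names(contigs)) {
    h1 <- six_frame_scan(contigs[[id]], reps, cfg, contig_id = id)
    fams <- refset$refs$family[match(h1$query_id[order(-h1$score)],
                                     refset$refs$id)]
    fams <- utils::head(unique(fams[!is.na(fams)]), top_families)
    more <- refset$refs[refset$refs$family %in% fams &
                          !refset$refs$id %in% reps$id, , drop = FALSE]
    h2 <- if (nrow(more))
      six_frame_scan(contigs[[id]], more, cfg, contig_id = id)
    else empty_hits()
    out[[id]] <- rbind(h1, h2)
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$span_lo), , drop = FALSE]
}
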