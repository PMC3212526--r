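# Two-stage conserved-site filter: align candidates to the reference profile,
# score the 19 conserved sites, and delineate the four motif sub-regions.

#' Align a candidate motif to the reference profile
#'
#' Global alignment with free end gaps of the candidate against the profile's
#' consensus sequence, returning a per-column residue lookup (profile column
#' -> candidate residue index). Candidates shorter than half the profile
#' width are flagged unalignable.
#'
#' @param candidate Amino-acid string.
#' @param profile A `conserved_profile` (see [build_conserved_profile()]).
#' @param substitution_matrix,gap_opening,gap_extension Alignment scoring
#'   parameters (the contract is the site evaluation, not any particular
#'   aligner's output string; penalties are therefore fixed configuration).
#' @return A `profile_alignment`: list with `map` (integer vector of length
#'   `profile$width`; `NA` where the candidate has a gap), `candidate`,
#'   `score`, `unalignable`.
#' @export
align_to_profile <- function(candidate, profile,
                             substitution_matrix = "BLOSUM62",
                             gap_opening = 10, gap_extension = 2) {
  if (!nchar(candidate)) stop("empty candidate sequence")
  width <- profile$width
  out <- list(candidate = candidate, map = rep(NA_integer_, width),
              score = -Inf, unalignable = FALSE)
  class(out) <- "profile_alignment"
  if (nchar(candidate) < width / 2) {
    out$unalignable <- TRUE
    return(out)
  }
  mat <- score_matrix(substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(candidate), Biostrings::AAString(profile$consensus),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  ps <- split_chars(as.character(Biostrings::pattern(pa)))
  ss <- split_chars(as.character(Biostrings::subject(pa)))
  pc <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  sc <- Biostrings::start(Biostrings::subject(pa)) - 1L
  map <- rep(NA_integer_, width)
  for (k in seq_along(ps)) {
    if (ps[k] != "-") pc <- pc + 1L
    if (ss[k] != "-") {
      sc <- sc + 1L
      if (ps[k] != "-") map[sc] <- pc
    }
  }
  out$map <- map
  out$score <- Biostrings::score(pa)
  out
}

#' Evaluate a candidate at the 19 conserved sites
#'
#' Counts how many of the profile's conserved sites carry a residue from the
#' site's conserved set in the aligned candidate; sites aligned to a gap
#' count as variations. `matches + variations = 19` always.
#'
#' @param alignment A `profile_alignment` from [align_to_profile()].
#' @param profile The `conserved_profile` used for the alignment.
#' @param candidate_id Optional label carried through to the result.
#' @return A one-row data frame: `candidate_id`, `matches`, `variations`.
#' @export
evaluate_sites <- function(alignment, profile, candidate_id = NA_character_) {
  res <- split_chars(alignment$candidate)
  n_match <- 0L
  for (k in seq_along(profile$sites)) {
    idx <- alignment$map[profile$sites[k]]
    if (!is.na(idx) && res[idx] %in% profile$residues[[k]])
      n_match <- n_match + 1L
  }
  data.frame(candidate_id = candidate_id, matches = n_match,
             variations = length(profile$sites) - n_match,
             stringsAsFactors = FALSE)
}

#' Apply the two-stage conserved-site filter
#'
#' Stage 1 marks candidates with fewer than `var_threshold` variations as
#' potential bHLH members; stage 2 discards candidates with fewer than
#' `match_threshold` conserved residues. With the survey's published
#' thresholds (variations < 9, matches >= 10) the two stages are not
#' complementary (variations < 9 already implies matches >= 11); both are
#' applied sequentially as published, and candidates caught by exactly one
#' stage are reported in the `stage` column.
#'
#' @param evals Data frame of site evaluations (rows from [evaluate_sites()]).
#' @param var_threshold Stage-1 rule: keep if `variations < var_threshold`
#'   (default 9).
#' @param match_threshold Stage-2 rule: discard if `matches < match_threshold`
#'   (default 10).
#' @return List with data frames `accepted` and `discarded`; both carry a
#'   `verdict` and `stage` column.
#' @export
apply_filter <- function(evals, var_threshold = 9, match_threshold = 10) {
  potential <- evals$variations < var_threshold
  survives2 <- evals$matches >= match_threshold
  accepted <- potential & survives2
  stage <- ifelse(accepted, "pass",
                  ifelse(!potential & !survives2, "both",
                         ifelse(!potential, "stage1", "stage2")))
  if (any(potential & !survives2))
    message(sum(potential & !survives2),
            " candidate(s) passed stage 1 but fell below the stage-2 ",
            "conserved-residue threshold")
  evals$verdict <- ifelse(accepted, "accepted", "discarded")
  evals$stage <- stage
  list(accepted = evals[accepted, , drop = FALSE],
       discarded = evals[!accepted, , drop = FALSE])
}

#' Delineate basic/helix1/loop/helix2 on a candidate
#'
#' Maps the profile's region template through the candidate's alignment:
#' candidate residues aligned to a template column take that column's region;
#' inserted residues inherit the region of the preceding aligned column.
#' Returns four contiguous intervals covering the candidate.
#'
#' @param alignment A `profile_alignment`.
#' @param template Region template (default the profile's own, falling back
#'   to [bhlh_region_template()]).
#' @param profile Optional `conserved_profile` supplying the template.
#' @return Named list of 1-based inclusive `c(start, end)` intervals
#'   (`basic`, `helix1`, `loop`, `helix2`); empty regions have `NA` bounds.
#' @export
delineate_regions <- function(alignment, profile = NULL, template = NULL) {
  if (alignment$unalignable) stop("candidate is unalignable to the profile")
  template <- template %||% (if (!is.null(profile)) profile$region_template) %||%
    bhlh_region_template()
  n <- nchar(alignment$candidate)
  col_region <- character(0)
  for (r in names(template))
    col_region[template[[r]][1]:template[[r]][2]] <- r
  region <- rep(NA_character_, n)
  for (col in which(!is.na(alignment$map)))
    region[alignment$map[col]] <- col_region[col]
  # unaligned candidate residues inherit the previous residue's region
  last <- NA_character_
  for (i in seq_len(n)) {
    if (is.na(region[i])) region[i] <- last else last <- region[i]
  }
  # leading unaligned residues inherit the first assigned region
  first <- region[!is.na(region)][1]
  region[is.na(region)] <- first
  out <- lapply(REGION_LEVELS, function(r) {
    w <- which(region == r)
    if (!length(w)) c(NA_integer_, NA_integer_) else range(w)
  })
  names(out) <- REGION_LEVELS
  out
}

#' Run the conserved-site filter over a hit table
#'
#' Convenience driver: aligns every hit's translated sequence to the profile,
#' evaluates the 19 sites and applies the two-stage filter.
#'
#' @param hits Hit table from [six_frame_scan()] (or any data frame with
#'   `translated_seq` and a label column).
#' @param profile A `conserved_profile`.
#' @param id_col Column used as candidate label (default row names built from
#'   contig/span).
#' @inheritParams apply_filter
#' @return List with `accepted`, `discarded` (as in [apply_filter()]) and
#'   `alignments` (named list of `profile_alignment`s).
#' @export
filter_hits <- function(hits, profile, id_col = NULL,
                        var_threshold = 9, match_threshold = 10) {
  # ids must stay Newick-safe (no ":", "-", ",", parentheses)
  ids <- if (!is.null(id_col)) hits[[id_col]]
  else paste0(hits$contig, "_", hits$span_lo, "_", hits$span_hi,
              ifelse(hits$strand == "+", "p", "m"))
  alns <- list(); evals <- list()
  for (i in seq_len(nrow(hits))) {
    aln <- align_to_profile(hits$translated_seq[i], profile)
    alns[[ids[i]]] <- aln
    evals[[i]] <- if (aln$unalignable)
      data.frame(candidate_id = ids[i], matches = 0L,
                 variations = length(profile$sites), stringsAsFactors = FALSE)
    else evaluate_sites(aln, profile, ids[i])
  }
  evals <- do.call(rbind, evals)
  res <- apply_filter(evals, var_threshold, match_threshold)
  res$alignments <- alns
  res
}
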