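# In-group phylogenetic ortholog assignment: candidate + related reference
# members + outgroup, three tree methods with bootstrap, pairwise-monophyly
# partner detection, and the four-outcome categorization.

#' Orthology-caller configuration
#'
#' @param nj_reps,mp_reps,ml_reps Bootstrap replicates per method (survey
#'   defaults: NJ 1,000; MP 100; the ML-surrogate uses 100 as the analog of
#'   puzzling support).
#' @param seed Integer seed (each method derives its own stream from it).
#' @param support_threshold Bootstrap value that must be exceeded (strictly)
#'   for a method to count as supporting; the survey's rule reads
#'   "exceed 50", so the boundary value 50 counts as weak.
#' @param min_refs,max_refs In-group size bounds used by [select_ingroup()].
#' @param cost Step matrix for the NJ method.
#' @return An `orthology_config` list.
#' @export
orthology_config <- function(nj_reps = 1000, mp_reps = 100, ml_reps = 100,
                             seed = 1, support_threshold = 50,
                             min_refs = 4, max_refs = 6,
                             cost = step_matrix_pam250()) {
  structure(list(nj_reps = nj_reps, mp_reps = mp_reps, ml_reps = ml_reps,
                 seed = seed, support_threshold = support_threshold,
                 min_refs = min_refs, max_refs = max_refs, cost = cost),
            class = "orthology_config")
}

# Map every sequence onto the profile coordinate system (gap-padded strings
# of equal length) so mixed-length inputs can enter tree building.
align_set <- function(seqs, profile = NULL) {
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  if (is.null(profile))
    stop("sequences differ in length; supply a conserved_profile to align them")
  out <- vapply(seqs, function(s) {
    aln <- align_to_profile(s, profile)
    if (aln$unalignable) return(strrep("-", profile$width))
    res <- split_chars(s)
    paste(ifelse(is.na(aln$map), "-", res[pmax(aln$map, 1L)]), collapse = "")
  }, "")
  names(out) <- names(seqs)
  out
}

#' Build the global reference tree
#'
#' NJ tree (step-matrix distances) over all candidates, all reference motifs
#' and the outgroup; the survey's equivalent of the global candidate/mouse
#' tree that guides in-group selection.
#'
#' @param candidates Named character vector of candidate motif sequences.
#' @param refset Reference set list (`refs`, `outgroup`), e.g. from
#'   [synthetic_reference_set()].
#' @param profile Optional `conserved_profile` for aligning mixed-length
#'   sequences.
#' @param cost Step matrix.
#' @return A `phylo` tree.
#' @export
global_reference_tree <- function(candidates, refset, profile = NULL,
                                  cost = step_matrix_pam250()) {
  seqs <- c(candidates,
            stats::setNames(refset$refs$sequence, refset$refs$id),
            stats::setNames(refset$outgroup$sequence, refset$outgroup$id))
  seqs <- align_set(seqs, profile)
  neighbor_joining(pairwise_distances(seqs, cost))
}

#' Select the in-group for a candidate
#'
#' Walks up from the candidate in the outgroup-rooted global tree and takes
#' the smallest enclosing clade holding at least `min_refs` reference
#' motifs; if the clade holds more than `max_refs`, the references closest
#' to the candidate (patristic distance) are kept.
#'
#' @param candidate_id Candidate tip label.
#' @param tree Global `phylo` tree containing candidate, references and
#'   outgroup.
#' @param refs A `bhlh_refset` (reference ids are taken from it).
#' @param outgroup_id Outgroup tip label.
#' @param min_refs,max_refs In-group size bounds.
#' @return Character vector of selected reference ids.
#' @export
select_ingroup <- function(candidate_id, tree, refs, outgroup_id,
                           min_refs = 4, max_refs = 6) {
  if (!candidate_id %in% tree$tip.label)
    stop("candidate '", candidate_id, "' is not in the global tree")
  rt <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  cl <- phylo_clades(rt)
  cl <- cl[vapply(cl, function(s) candidate_id %in% s, TRUE)]
  cl <- cl[order(lengths(cl))]
  sel <- character(0)
  for (s in cl) {
    sel <- intersect(s, refs$id)
    if (length(sel) >= min_refs) break
  }
  if (length(sel) < min_refs) sel <- intersect(rt$tip.label, refs$id)
  if (length(sel) > max_refs) {
    d <- stats::cophenetic(tree)[candidate_id, sel]
    sel <- sel[order(d, sel)][seq_len(max_refs)]
  }
  sel
}

method_label <- c(nj = "NJ", mp = "MP", ml = "ML")

#' Run the three-method in-group analysis for one candidate
#'
#' Builds NJ, MP and ML-surrogate trees with bootstrap over the candidate,
#' its in-group references and the outgroup. Per method, the partner is the
#' unique reference forming a two-taxon monophyletic clade with the
#' candidate in the outgroup-rooted reference tree (bootstrap = support of
#' that clade); failing that, the candidate is flagged `n/m*` when it is
#' monophyletic with all present members of some family, and `n/m`
#' otherwise.
#'
#' @param candidate_id Candidate label (must name an element of `seqs`).
#' @param seqs Named character vector: candidate, in-group references and
#'   outgroup (aligned).
#' @param outgroup_id Outgroup label.
#' @param family_of Named character vector mapping reference ids to family
#'   names.
#' @param cfg An [orthology_config()].
#' @return Data frame with one row per method: `method`, `partner`,
#'   `bootstrap`, `flag` (`mono_with_partner`, `n/m*`, `n/m`).
#' @export
run_ingroup_analysis <- function(candidate_id, seqs, outgroup_id, family_of,
                                 cfg = orthology_config()) {
  ingroup <- setdiff(names(seqs), c(candidate_id, outgroup_id))
  if (length(ingroup) < 2L) stop("in-group must hold at least 2 references")
  if (!outgroup_id %in% names(seqs)) stop("outgroup sequence missing")
  sorted_labels <- sort(names(seqs))
  reps <- c(nj = cfg$nj_reps, mp = cfg$mp_reps, ml = cfg$ml_reps)
  rows <- lapply(names(reps), function(b) {
    bs <- bootstrap_support(seqs, builder = b, replicates = reps[[b]],
                            seed = cfg$seed + match(b, names(reps)),
                            cost = cfg$cost)
    rt <- ape::root(bs$tree, outgroup = outgroup_id, resolve.root = TRUE)
    cl <- phylo_clades(rt)
    enclosing <- cl[vapply(cl, function(s) candidate_id %in% s, TRUE)]
    enclosing <- enclosing[order(lengths(enclosing))]
    cherry <- if (length(enclosing) && length(enclosing[[1]]) == 2L)
      setdiff(enclosing[[1]], candidate_id) else NULL
    if (!is.null(cherry) && cherry != outgroup_id) {
      supp <- bs$support[canonical_split(c(candidate_id, cherry),
                                         sorted_labels)]
      data.frame(method = method_label[[b]], partner = cherry,
                 bootstrap = unname(supp), flag = "mono_with_partner",
                 stringsAsFactors = FALSE)
    } else {
      fams <- unique(family_of[ingroup])
      star <- FALSE
      for (f in fams) {
        members <- ingroup[family_of[ingroup] == f]
        if (length(members) < 2L) next
        if (any(vapply(cl, function(s)
          setequal(s, c(candidate_id, members)), TRUE))) { star <- TRUE; break }
      }
      data.frame(method = method_label[[b]], partner = NA_character_,
                 bootstrap = NA_real_, flag = if (star) "n/m*" else "n/m",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Categorize a candidate's method results
#'
#' Implements the survey's four outcome categories. With S the number of
#' methods supporting the same partner with bootstrap strictly above the
#' threshold: category 1 when all three methods agree (S = 3), category 2
#' when exactly two do, category 3 when at least one method found a partner
#' but fewer than two support it strongly, and category 4 when no method
#' found a partner (triggering the whole-protein fallback).
#'
#' @param results Three-row method-result data frame from
#'   [run_ingroup_analysis()].
#' @param threshold Support threshold (exceeded strictly; default 50).
#' @param whole_protein Set when `results` come from the whole-protein
#'   fallback run; any partner found then yields category 4.
#' @return List with `category`, `partner`, `n_support`, `pattern` (which
#'   methods support, e.g. `"NJ+ML"`), and display `tokens` per method.
#' @export
categorize <- function(results, threshold = 50, whole_protein = FALSE) {
  has_partner <- !is.na(results$partner)
  tokens <- ifelse(has_partner, as.character(round(results$bootstrap)),
                   results$flag)
  names(tokens) <- results$method
  if (!any(has_partner))
    return(list(category = 4L, partner = NA_character_, n_support = 0L,
                pattern = "", tokens = tokens))
  main <- if (has_partner[1]) results$partner[1] else
    results$partner[has_partner][1]
  strong <- has_partner & results$partner == main &
    results$bootstrap > threshold
  n <- sum(strong)
  category <- if (whole_protein) 4L else if (n == 3L) 1L else if (n == 2L) 2L else 3L
  list(category = category, partner = main, n_support = n,
       pattern = paste(results$method[strong], collapse = "+"),
       tokens = tokens)
}

#' Assign families to candidates by in-group phylogenetic analysis
#'
#' Full driver: builds the global reference tree, selects each candidate's
#' in-group, runs the three-method analysis, categorizes, and (for category
#' 4) reruns with whole-protein sequences when supplied. The result is a
#' survey-table-shaped data frame.
#'
#' @param candidates Named character vector of candidate motif sequences.
#' @param refset Reference set list (`refs`, `catalog`, `outgroup`).
#' @param cfg An [orthology_config()].
#' @param profile Optional profile for aligning mixed-length sequences.
#' @param whole_proteins Optional named character vector of full-length
#'   sequences (reference ids, outgroup id, candidate ids) used by the
#'   category-4 fallback.
#' @return Data frame with columns `gene`, `family`, `mouse_homologue`
#'   (partner id), `nj`, `mp`, `ml` (bootstrap values or `n/m`/`n/m*`
#'   tokens), `category`, `pattern`, `accession`.
#' @export
assign_orthologs <- function(candidates, refset, cfg = orthology_config(),
                             profile = NULL, whole_proteins = NULL) {
  if (!length(candidates)) return(empty_calls())
  refs <- refset$refs
  family_of <- stats::setNames(refs$family, refs$id)
  outgroup_id <- refset$outgroup$id[1]
  gtree <- global_reference_tree(candidates, refset, profile)
  aligned <- align_set(c(candidates,
                         stats::setNames(refs$sequence, refs$id),
                         stats::setNames(refset$outgroup$sequence, outgroup_id)),
                       profile)
  rows <- lapply(names(candidates), function(id) {
    sel <- select_ingroup(id, gtree, refs, outgroup_id,
                          cfg$min_refs, cfg$max_refs)
    seqs <- aligned[c(id, sel, outgroup_id)]
    res <- run_ingroup_analysis(id, seqs, outgroup_id, family_of, cfg)
    cat_ <- categorize(res, cfg$support_threshold)
    if (cat_$category == 4L && !is.null(whole_proteins)) {
      ids <- c(id, sel, outgroup_id)
      if (all(ids %in% names(whole_proteins))) {
        wp <- align_set(whole_proteins[ids], profile = NULL)
        res <- run_ingroup_analysis(id, wp, outgroup_id, family_of, cfg)
        cat_ <- categorize(res, cfg$support_threshold, whole_protein = TRUE)
      }
    }
    fam <- if (!is.na(cat_$partner)) unname(family_of[cat_$partner])
    else NA_character_
    data.frame(gene = id, family = fam %||% NA_character_,
               mouse_homologue = cat_$partner,
               nj = cat_$tokens[["NJ"]], mp = cat_$tokens[["MP"]],
               ml = cat_$tokens[["ML"]], category = cat_$category,
               pattern = cat_$pattern, accession = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_calls <- function() {
  data.frame(gene = character(), family = character(),
             mouse_homologue = character(), nj = character(),
             mp = character(), ml = character(), category = integer(),
             pattern = character(), accession = character(),
             stringsAsFactors = FALSE)
}

#' Load the packaged survey orthology table
#'
#' Transcription of the published survey's per-gene table: family, gene,
#' mouse homologue, NJ/MP/ML bootstrap columns (with `n/m` and `n/m*`
#' tokens), accession, GenBank annotation, and a flag for the four genes
#' whose orthology was defined with whole-protein sequences.
#'
#' @param path TSV path (defaults to the packaged fixture).
#' @return Data frame of 107 rows.
#' @export
load_table1 <- function(path = census_fixture("table1_orthology.tsv")) {
  t1 <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("family", "gene", "mouse_homologue", "nj", "mp", "ml",
            "accession", "annotation", "whole_protein")
  miss <- setdiff(need, names(t1))
  if (length(miss)) stop("orthology table lacks column(s): ",
                         paste(miss, collapse = ", "))
  t1
}

fixture_method_results <- function(row) {
  token <- c(NJ = row$nj, MP = row$mp, ML = row$ml)
  num <- suppressWarnings(as.numeric(token))
  data.frame(method = names(token),
             partner = ifelse(is.na(num), NA_character_, row$mouse_homologue),
             bootstrap = num,
             flag = ifelse(is.na(num), token, "mono_with_partner"),
             stringsAsFactors = FALSE)
}

#' Categorize the rows of a survey orthology table
#'
#' Applies [categorize()] to each fixture row (whole-protein-flagged rows
#' map to category 4, as their printed bootstrap values come from the
#' fallback analysis).
#'
#' @param t1 Data frame from [load_table1()].
#' @param threshold Support threshold (default 50).
#' @return `t1` with added integer column `category`.
#' @export
categorize_table1 <- function(t1, threshold = 50) {
  t1$category <- vapply(seq_len(nrow(t1)), function(i) {
    categorize(fixture_method_results(t1[i, ]), threshold,
               whole_protein = t1$whole_protein[i] == 1)$category
  }, 0L)
  t1
}
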