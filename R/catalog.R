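# Reference catalog: family -> high-order-group table, reference bHLH motif
# sets, and the conserved-site profile used by the filtering stage.

#' The four sub-regions of the bHLH motif
#'
#' Default delineation of the basic, helix 1, loop and helix 2 sub-regions on
#' the 60-residue motif coordinate system used by the package's profile.
#' Intervals are 1-based, inclusive, contiguous and cover the motif.
#'
#' @return Named list of length-2 integer vectors (`basic`, `helix1`, `loop`,
#'   `helix2`).
#' @export
bhlh_region_template <- function() {
  list(basic  = c(1L, 13L),
       helix1 = c(14L, 28L),
       loop   = c(29L, 44L),
       helix2 = c(45L, 60L))
}

REGION_LEVELS <- c("basic", "helix1", "loop", "helix2")

#' Default conserved-site positions
#'
#' The 19 positions on the 60-residue motif coordinate system at which
#' candidate sequences are scored against the reference consensus. The exact
#' identity of the canonical conserved sites is an alignment convention rather
#' than a measurable quantity, so the positions are configuration, not
#' hard-coded: this default includes the two most conserved motif sites (23
#' and 59) and weights the basic region and helix 2 more heavily than the
#' variable loop.
#'
#' @return Strictly increasing integer vector of length 19.
#' @export
default_conserved_sites <- function() {
  c(5L, 8L, 9L, 12L, 13L, 16L, 19L, 23L, 26L, 28L,
    33L, 38L, 45L, 48L, 49L, 52L, 55L, 56L, 59L)
}

#' Load a family-to-group catalog
#'
#' Reads a two-column TSV (`family`, `group`) mapping bHLH family names to the
#' high-order groups A-F. The packaged default is the full 45-family animal
#' catalog (22 families in group A, 12 in B, 7 in C, 1 in D, 2 in E, 1 in F).
#'
#' @param path TSV file; defaults to the packaged animal catalog.
#' @return A `family_catalog`: data frame with columns `family` and `group`.
#' @export
load_family_catalog <- function(path = census_fixture("family_groups.tsv")) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("family", "group") %in% names(cat)))
    stop("catalog must have columns 'family' and 'group': ", path)
  bad <- setdiff(unique(cat$group), LETTERS[1:6])
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(cat$family))
    stop("duplicated family in catalog: ", cat$family[duplicated(cat$family)][1])
  structure(cat[, c("family", "group")], class = c("family_catalog", "data.frame"))
}

#' Families per high-order group
#'
#' @param catalog A `family_catalog`.
#' @return Named integer vector, number of families per group A-F.
#' @export
group_family_counts <- function(catalog) {
  tab <- table(factor(catalog$group, levels = LETTERS[1:6]))
  stats::setNames(as.integer(tab), names(tab))
}

family_group <- function(catalog, family) {
  g <- catalog$group[match(family, catalog$family)]
  if (anyNA(g)) stop("family absent from catalog: ",
                     paste(unique(family[is.na(g)]), collapse = ", "))
  g
}

new_refset <- function(id, family, group, sequence,
                       template = bhlh_region_template()) {
  refs <- data.frame(id = as.character(id), family = as.character(family),
                     group = as.character(group), sequence = as.character(sequence),
                     stringsAsFactors = FALSE)
  structure(refs, region_template = template,
            class = c("bhlh_refset", "data.frame"))
}

validate_refset <- function(refs) {
  len <- nchar(refs$sequence)
  bad <- which(len < 50 | len > 75)
  if (length(bad))
    stop("motif length outside [50, 75] for record '", refs$id[bad[1]],
         "' (", len[bad[1]], " aa)")
  if (anyDuplicated(refs$id))
    stop("duplicated motif id: ", refs$id[duplicated(refs$id)][1])
  chars <- unique(unlist(strsplit(refs$sequence, "")))
  odd <- setdiff(chars, c(AA_ALPHABET, "X", "-"))
  if (length(odd)) stop("non amino-acid character(s) in sequences: ",
                        paste(odd, collapse = ""))
  invisible(refs)
}

#' Load a reference motif set
#'
#' Reads a FASTA file of reference bHLH motifs whose headers encode
#' `id|family`, validates every record (motif length within 50-75 residues,
#' amino-acid alphabet, family present in the catalog) and attaches each
#' family's high-order group.
#'
#' @param path FASTA file.
#' @param catalog A `family_catalog` used to validate family labels.
#' @return A `bhlh_refset`: data frame with columns `id`, `family`, `group`,
#'   `sequence` and a `region_template` attribute.
#' @export
load_reference_set <- function(path, catalog = load_family_catalog()) {
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) {
    warning("empty reference FASTA: ", path)
    return(new_refset(character(), character(), character(), character()))
  }
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("malformed FASTA header (expected 'id|family') at record ",
         which(nf != 2L)[1], ": '", names(seqs)[nf != 2L][1], "'")
  id <- vapply(parts, `[`, "", 1L)
  family <- vapply(parts, `[`, "", 2L)
  refs <- new_refset(id, family, family_group(catalog, family),
                     as.character(seqs))
  validate_refset(refs)
  refs
}

#' Write a reference motif set as FASTA
#'
#' Inverse of [load_reference_set()]: headers are written as `id|family`.
#'
#' @param refs A `bhlh_refset`.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(refs, path) {
  x <- Biostrings::AAStringSet(refs$sequence)
  names(x) <- paste(refs$id, refs$family, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Build a conserved-site profile from aligned references
#'
#' For each of the 19 conserved sites, the set of residues regarded as
#' "conserved" is every residue whose frequency among the references reaches
#' `cutoff` (falling back to the modal residue(s) when no residue does, so the
#' set is never empty). A per-column modal consensus over the full alignment
#' width is also recorded; it is the anchor sequence that candidates are
#' aligned against.
#'
#' @param refs A `bhlh_refset` whose sequences share a common (aligned)
#'   coordinate system, i.e. equal lengths.
#' @param site_positions Integer vector of 19 strictly increasing alignment
#'   positions.
#' @param cutoff Frequency threshold for a residue to count as conserved at a
#'   site (default 0.5).
#' @return A `conserved_profile`: list with elements `sites`, `residues` (one
#'   character vector per site), `consensus`, `width`, `cutoff` and the region
#'   template.
#' @export
build_conserved_profile <- function(refs, site_positions = default_conserved_sites(),
                                    cutoff = 0.5) {
  if (nrow(refs) < 2L) stop("need at least 2 reference motifs to build a profile")
  m <- seq_matrix(refs$sequence)
  width <- ncol(m)
  site_positions <- as.integer(site_positions)
  if (length(site_positions) != 19L)
    stop("exactly 19 conserved site positions are required, got ",
         length(site_positions))
  if (is.unsorted(site_positions, strictly = TRUE))
    stop("conserved site positions must be strictly increasing")
  if (any(site_positions < 1L | site_positions > width))
    stop("conserved site position outside alignment width [1, ", width, "]")
  col_sets <- function(j) {
    res <- m[, j]
    res <- res[res %in% AA_ALPHABET]
    tab <- table(res) / length(res)
    keep <- names(tab)[tab >= cutoff]
    if (!length(keep)) keep <- names(tab)[tab == max(tab)]
    sort(keep)
  }
  residues <- lapply(site_positions, col_sets)
  consensus <- vapply(seq_len(width), function(j) {
    res <- m[, j]
    res <- res[res %in% AA_ALPHABET]
    if (!length(res)) return("X")
    names(sort(table(res), decreasing = TRUE))[1]
  }, "")
  structure(list(sites = site_positions, residues = residues,
                 consensus = paste(consensus, collapse = ""),
                 width = width, cutoff = cutoff,
                 region_template = attr(refs, "region_template") %||% bhlh_region_template()),
            class = "conserved_profile")
}

#' @export
print.conserved_profile <- function(x, ...) {
  cat("Conserved-site profile: ", length(x$sites), " sites on a ", x$width,
      "-column alignment (cutoff ", x$cutoff, ")\n", sep = "")
  sets <- vapply(x$residues, paste, "", collapse = "/")
  cat(paste0(x$sites, ":", sets, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.bhlh_refset <- function(x, ...) {
  cat("bHLH reference set: ", nrow(x), " motifs, ",
      length(unique(x$family)), " families\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
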