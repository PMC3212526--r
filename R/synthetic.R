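# Synthetic-genome generator: plants family-labelled, intron-split bHLH genes
# on both strands of random background contigs, with exact ground truth.

#' Consensus bHLH motif used by the synthetic generator
#'
#' A fixed 60-residue basic helix-loop-helix consensus laid out on the
#' package's region template (basic 1-13, helix 1 14-28, loop 29-44, helix 2
#' 45-60). Synthetic reference families are generated by mutating this
#' sequence away from the conserved sites.
#'
#' @return A 60-character amino-acid string.
#' @export
bhlh_consensus <- function() {
  paste0("ADRRKAATMRERR",     # basic
         "LSKVNEAFETLKRCT",   # helix 1
         "SSNPNQRLPKVEILRN",  # loop
         "AIRYIEGLQALLRDQD")  # helix 2
}

# Fixed reverse-translation codon table (one codon per residue). Codon usage
# bias is irrelevant to the survey logic; a fixed table keeps the generator
# deterministic.
CODON_TABLE <- c(A = "GCC", R = "CGG", N = "AAC", D = "GAC", C = "TGC",
                 Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
                 L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
                 S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

#' Reverse-translate an amino-acid string
#'
#' Uses a fixed one-codon-per-residue table so the result is deterministic.
#'
#' @param aa Amino-acid string (standard 20-letter alphabet).
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa) {
  res <- split_chars(aa)
  bad <- setdiff(res, names(CODON_TABLE))
  if (length(bad)) stop("cannot reverse-translate residue(s): ",
                        paste(bad, collapse = ""))
  paste(CODON_TABLE[res], collapse = "")
}

#' Mutate a motif by per-site substitution
#'
#' Each position is substituted, independently with probability `sub_rate`, by
#' a uniformly chosen different residue. With `protect_conserved` the 19
#' conserved sites are never touched, so mutated motifs still pass the
#' conserved-site filter by construction.
#'
#' @param seq Amino-acid string (or a single-row `bhlh_refset`).
#' @param sub_rate Per-site substitution probability in \[0, 1\].
#' @param protect_conserved Protect the conserved sites? Default `TRUE`.
#' @param sites Conserved site positions (default [default_conserved_sites()]).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return The mutated amino-acid string.
#' @export
mutate_motif <- function(seq, sub_rate, protect_conserved = TRUE,
                         sites = default_conserved_sites(), seed = NULL) {
  if (is.data.frame(seq)) seq <- seq$sequence[1]
  if (sub_rate < 0 || sub_rate > 1) stop("sub_rate must be within [0, 1]")
  with_seed(seed, {
    res <- split_chars(seq)
    hit <- stats::runif(length(res)) < sub_rate
    if (protect_conserved) hit[sites[sites <= length(res)]] <- FALSE
    for (i in which(hit)) res[i] <- sample(setdiff(AA_ALPHABET, res[i]), 1L)
    paste(res, collapse = "")
  })
}

#' Generate a synthetic reference motif set
#'
#' Builds a stand-in for the published reference catalogs: each family is a
#' prototype derived from the bHLH consensus by mutation at non-conserved
#' sites (`family_divergence`), and family members are lighter mutations of
#' the prototype (`member_divergence`, default 0.25: real bHLH paralogs
#' within a family typically share 60-85 percent motif identity). Families are spread over the
#' high-order groups A-F in roughly the proportions of the animal catalog. A
#' distant outgroup motif (analogous to the rice R-family motif used to root
#' in-group trees) is generated alongside.
#'
#' @param n_families Number of families (default 15).
#' @param members_per_family Motifs per family (default 3).
#' @param family_divergence Substitution rate consensus -> family prototype.
#' @param member_divergence Substitution rate prototype -> member.
#' @param seed Integer seed; the set is fully deterministic given it.
#' @return List with `refs` (a `bhlh_refset`), `catalog` (a
#'   `family_catalog`), and `outgroup` (data frame with `id`, `sequence`).
#' @export
synthetic_reference_set <- function(n_families = 15, members_per_family = 3,
                                    family_divergence = 0.35,
                                    member_divergence = 0.25, seed = 42) {
  with_seed(seed, {
    # group proportions mirroring the 45-family animal catalog (22/12/7/1/2/1)
    groups <- rep(LETTERS[1:6],
                  pmax(1L, round(n_families * c(22, 12, 7, 1, 2, 1) / 45)))[seq_len(n_families)]
    fam <- sprintf("SynFam%02d", seq_len(n_families))
    catalog <- structure(data.frame(family = fam, group = groups,
                                    stringsAsFactors = FALSE),
                         class = c("family_catalog", "data.frame"))
    id <- character(0); family <- character(0); sequence <- character(0)
    for (i in seq_len(n_families)) {
      proto <- mutate_motif(bhlh_consensus(), family_divergence)
      for (m in seq_len(members_per_family)) {
        id <- c(id, sprintf("%s_m%d", fam[i], m))
        family <- c(family, fam[i])
        sequence <- c(sequence, mutate_motif(proto, member_divergence))
      }
    }
    refs <- new_refset(id, family, family_group(catalog, family), sequence)
    out <- data.frame(id = "OsRa_syn",
                      sequence = mutate_motif(bhlh_consensus(), 0.55),
                      stringsAsFactors = FALSE)
    list(refs = refs, catalog = catalog, outgroup = out)
  })
}

#' Synthetic whole-protein sequences for the fallback analysis
#'
#' Fabricates full-length proteins by flanking each motif with
#' family-conserved N- and C-terminal segments of fixed length, providing the
#' input that the whole-protein fallback of the orthology caller needs in
#' synthetic mode.
#'
#' @param refset Result of [synthetic_reference_set()].
#' @param flank Flank length in residues (each side).
#' @param seed Integer seed.
#' @return Named character vector of whole-protein sequences, one per
#'   reference id (plus the outgroup id).
#' @export
synthetic_whole_proteins <- function(refset, flank = 40, seed = 7) {
  with_seed(seed, {
    fams <- unique(refset$refs$family)
    flanks <- lapply(fams, function(f)
      list(n = paste(sample(AA_ALPHABET, flank, TRUE), collapse = ""),
           c = paste(sample(AA_ALPHABET, flank, TRUE), collapse = "")))
    names(flanks) <- fams
    out <- vapply(seq_len(nrow(refset$refs)), function(i) {
      f <- flanks[[refset$refs$family[i]]]
      paste0(f$n, refset$refs$sequence[i], f$c)
    }, "")
    names(out) <- refset$refs$id
    og <- paste0(paste(sample(AA_ALPHABET, flank, TRUE), collapse = ""),
                 refset$outgroup$sequence[1],
                 paste(sample(AA_ALPHABET, flank, TRUE), collapse = ""))
    c(out, stats::setNames(og, refset$outgroup$id[1]))
  })
}

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Table 2-style frame label of a coding segment
#'
#' Plus-strand frames are numbered +1..+3 by offset of the segment's first
#' base from the contig start; minus-strand frames -1..-3 by offset of the
#' segment's 5' base from the contig end.
#'
#' @param start5 Genomic coordinate of the segment's 5' base (reading
#'   direction), 1-based.
#' @param strand `"+"` or `"-"`.
#' @param contig_len Contig length in bp.
#' @return Frame label such as `"+2"` or `"-1"`.
#' @export
segment_frame <- function(start5, strand, contig_len) {
  if (strand == "+") paste0("+", ((start5 - 1L) %% 3L) + 1L)
  else paste0("-", ((contig_len - start5) %% 3L) + 1L)
}

region_of_residue <- function(residue, template = bhlh_region_template()) {
  for (r in names(template))
    if (residue >= template[[r]][1] && residue <= template[[r]][2]) return(r)
  stop("residue ", residue, " outside the region template")
}

#' Realize a synthetic gene on a background contig
#'
#' Reverse-translates the motif, inserts introns (minimum 60 bp, `GT..AG`
#' terminal dinucleotides) after the planned codons, writes the gene onto the
#' background (as reverse complement for minus-strand genes) and records the
#' realized genomic segments: 1-based inclusive coordinates, minus-strand
#' segments in descending (reading) order, so that the coordinate gap between
#' consecutive segments reproduces each planned intron length exactly.
#'
#' @param spec List with `gene_id`, `family`, `motif_seq`, `intron_plan`
#'   (data frame with columns `codon`, `length`; 0-3 rows), `strand`,
#'   `contig_id`, `insertion_offset`.
#' @param background Background nucleotide string (overwritten in place).
#' @param occupied Optional matrix of already-used intervals (rows of
#'   start/end); overlap raises a placement error.
#' @return List with `contig` (updated sequence), `segments` (data frame with
#'   `start`, `end`, `frame` and the gap annotation columns `intron_region`,
#'   `intron_length`), `introns`, and `span` (interval used).
#' @export
realize_gene <- function(spec, background, occupied = NULL) {
  plan <- spec$intron_plan
  if (is.null(plan)) plan <- data.frame(codon = integer(), length = integer())
  L <- nchar(spec$motif_seq)
  if (nrow(plan) > 3L) stop("at most 3 introns per gene")
  if (nrow(plan)) {
    if (any(plan$length < 60)) stop("intron lengths must be >= 60 bp")
    if (is.unsorted(plan$codon, strictly = TRUE))
      stop("intron codon indices must be strictly increasing")
    if (any(plan$codon < 1L | plan$codon >= L))
      stop("intron codon indices must be interior to the motif")
  }
  cds <- reverse_translate(spec$motif_seq)
  bounds <- c(0L, plan$codon, L) * 3L               # exon boundaries in bp
  exons <- substring(cds, utils::head(bounds, -1L) + 1L, bounds[-1L])
  intron_seq <- vapply(plan$length, function(l)
    paste0("GT", random_dna(l - 4L), "AG"), "")
  gene <- exons[1L]
  for (i in seq_len(nrow(plan))) gene <- paste0(gene, intron_seq[i], exons[i + 1L])
  glen <- nchar(gene)
  o <- spec$insertion_offset
  if (o < 1L || o + glen - 1L > nchar(background))
    stop("background too short for gene '", spec$gene_id, "'")
  span <- c(o, o + glen - 1L)
  if (!is.null(occupied) && nrow(occupied))
    if (any(span[1] <= occupied[, 2] & span[2] >= occupied[, 1]))
      stop("placement error: gene '", spec$gene_id,
           "' overlaps an existing gene")
  ins <- if (spec$strand == "+") gene else revcomp(gene)
  contig <- paste0(substring(background, 1L, o - 1L), ins,
                   substring(background, o + glen, nchar(background)))
  # gene-local (coding-strand) exon intervals
  loc_start <- cumsum(c(1L, nchar(exons) + c(plan$length, integer(1))))[seq_along(exons)]
  loc_end <- loc_start + nchar(exons) - 1L
  if (spec$strand == "+") {
    g_start <- o + loc_start - 1L
    g_end <- o + loc_end - 1L
  } else {
    g_start <- o + glen - loc_start   # 5' base: descending coordinates
    g_end <- o + glen - loc_end
  }
  regions <- if (nrow(plan))
    vapply(plan$codon + 1L, region_of_residue, "",
           template = bhlh_region_template()) else character(0)
  segs <- data.frame(
    start = g_start, end = g_end,
    frame = vapply(g_start, segment_frame, "", strand = spec$strand,
                   contig_len = nchar(contig)),
    intron_region = c(regions, NA_character_),
    intron_length = c(plan$length, NA_integer_),
    stringsAsFactors = FALSE)
  introns <- if (nrow(plan))
    data.frame(index = seq_len(nrow(plan)), length = plan$length,
               region = regions, after_codon = plan$codon,
               stringsAsFactors = FALSE)
  else data.frame(index = integer(), length = integer(),
                  region = character(), after_codon = integer())
  list(contig = contig, segments = segs, introns = introns, span = span)
}

# Exons are kept at >= 8 codons (edges and between introns) so that every
# exon piece carries enough alignment signal to clear the scanner's sub-hit
# threshold; the survey logic itself does not depend on this.
plan_intron_positions <- function(L, n, min_edge = 8L, min_gap = 8L) {
  if (n == 0L) return(integer(0))
  lo <- min_edge + 1L; hi <- L - min_edge
  for (try in 1:100) {
    pos <- sort(sample(lo:hi, n))
    if (n == 1L || all(diff(pos) >= min_gap)) return(pos)
  }
  plan_intron_positions(L, n - 1L, min_edge, min_gap)
}

#' Generate a synthetic genome with planted bHLH genes
#'
#' Plants `n_genes` intron-split bHLH genes, one per contig, each derived from
#' a randomly chosen reference motif by per-site mutation with the conserved
#' sites protected, on a random strand, and appends one background-only decoy
#' contig. Deterministic for a fixed seed. Default condition parameters:
#' substitution rate 0.05, intron-count probabilities (0.56, 0.24, 0.18,
#' 0.02) matching the 60/26/19/2 proportions of the published survey,
#' log-normal intron lengths clamped to \[60, 45217\] bp, background GC 0.42.
#'
#' @param refset Result of [synthetic_reference_set()] (or compatible list
#'   with `refs` and `catalog`).
#' @param n_genes Number of planted genes.
#' @param sub_rate Per-site substitution rate applied to planted motifs.
#' @param protect_conserved Protect conserved sites while mutating.
#' @param intron_count_probs Probabilities of 0-3 introns per gene.
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters.
#' @param intron_range Clamp interval for intron lengths (bp).
#' @param gc Background GC fraction.
#' @param pad Range of random background padding on each side of a gene (bp).
#' @param family_weights Optional sampling weights over families.
#' @param seed Integer seed.
#' @return List with `contigs` (named character vector), `truth` (segment
#'   table with Table 2-style columns plus gene/family labels), `introns`
#'   (planned introns), `motifs` (planted motif per gene) and `specs`.
#' @export
generate_genome <- function(refset, n_genes = 20, sub_rate = 0.05,
                            protect_conserved = TRUE,
                            intron_count_probs = c(0.56, 0.24, 0.18, 0.02),
                            intron_meanlog = 7, intron_sdlog = 1.3,
                            intron_range = c(60, 45217), gc = 0.42,
                            pad = c(400, 1200), family_weights = NULL,
                            seed = 1) {
  refs <- refset$refs
  if (!nrow(refs)) stop("reference set is empty")
  with_seed(seed, {
    fams <- unique(refs$family)
    w <- family_weights %||% rep(1, length(fams))
    contigs <- character(0); truth <- list(); introns <- list()
    motifs <- character(0); specs <- list()
    for (g in seq_len(n_genes)) {
      fam <- sample(fams, 1L, prob = w)
      member <- refs[refs$family == fam, ][sample(sum(refs$family == fam), 1L), ]
      motif <- mutate_motif(member$sequence, sub_rate, protect_conserved)
      L <- nchar(motif)
      k <- sample(0:3, 1L, prob = intron_count_probs)
      pos <- plan_intron_positions(L, k)
      len <- integer(0)
      if (length(pos)) {
        len <- round(stats::rlnorm(length(pos), intron_meanlog, intron_sdlog))
        len <- pmin(pmax(len, intron_range[1]), intron_range[2])
      }
      strand <- sample(c("+", "-"), 1L)
      glen <- 3L * L + sum(len)
      pads <- sample(pad[1]:pad[2], 2L, replace = TRUE)
      contig_id <- sprintf("ctg%03d", g)
      gene_id <- sprintf("synth%03d", g)
      spec <- list(gene_id = gene_id, family = fam, member_id = member$id,
                   motif_seq = motif,
                   intron_plan = data.frame(codon = pos, length = len),
                   strand = strand, contig_id = contig_id,
                   insertion_offset = pads[1] + 1L)
      background <- random_dna(glen + sum(pads), gc)
      rg <- realize_gene(spec, background)
      contigs[contig_id] <- rg$contig
      seg <- rg$segments
      truth[[g]] <- data.frame(gene_id = gene_id, family = fam,
                               member_id = member$id, contig = contig_id,
                               strand = strand, seg = seq_len(nrow(seg)),
                               seg, stringsAsFactors = FALSE)
      if (nrow(rg$introns))
        introns[[g]] <- data.frame(gene_id = gene_id, rg$introns,
                                   stringsAsFactors = FALSE)
      motifs[gene_id] <- motif
      specs[[gene_id]] <- spec
    }
    contigs["ctg_bg"] <- random_dna(3000L, gc)
    list(contigs = contigs,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(gene_id = character(), family = character(),
                      member_id = character(), contig = character(),
                      strand = character(), seg = integer(),
                      start = integer(), end = integer(), frame = character(),
                      intron_region = character(), intron_length = integer()),
         introns = if (length(introns)) do.call(rbind, introns) else
           data.frame(gene_id = character(), index = integer(),
                      length = integer(), region = character(),
                      after_codon = integer()),
         motifs = motifs, specs = specs)
  })
}

#' Write synthetic contigs as FASTA
#'
#' @param genome Result of [generate_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write ground truth as GFF3 and a Table 2-style TSV
#'
#' The GFF3 carries one `gene` feature per planted gene and one `CDS` feature
#' per coding segment (1-based inclusive coordinates, strand column); the TSV
#' mirrors the published table's layout (contig, frame, coding regions,
#' intron location and length).
#'
#' @param genome Result of [generate_genome()].
#' @param gff_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, a list of the paths written.
#' @export
write_ground_truth <- function(genome, gff_path = NULL, tsv_path = NULL) {
  tr <- genome$truth
  if (!is.null(gff_path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE) ||
        !requireNamespace("GenomicRanges", quietly = TRUE))
      stop("rtracklayer/GenomicRanges are required to write GFF3")
    lo <- pmin(tr$start, tr$end); hi <- pmax(tr$start, tr$end)
    spans <- do.call(rbind, lapply(split(seq_len(nrow(tr)), tr$gene_id), function(i)
      data.frame(gene_id = tr$gene_id[i[1]], contig = tr$contig[i[1]],
                 strand = tr$strand[i[1]], start = min(lo[i]), end = max(hi[i]))))
    gr_gene <- GenomicRanges::GRanges(
      spans$contig,
      IRanges::IRanges(spans$start, spans$end),
      strand = spans$strand, type = "gene", ID = spans$gene_id)
    seg_len <- abs(tr$end - tr$start) + 1L
    phase <- unlist(lapply(split(seg_len, tr$gene_id)[unique(tr$gene_id)],
                           function(l) (3L - cumsum(c(0L, l[-length(l)])) %% 3L) %% 3L))
    gr_cds <- GenomicRanges::GRanges(
      tr$contig, IRanges::IRanges(lo, hi), strand = tr$strand,
      type = "CDS", ID = paste0(tr$gene_id, ".cds", tr$seg),
      Parent = tr$gene_id, phase = as.integer(phase))
    rtracklayer::export(c(gr_gene, gr_cds), gff_path, format = "gff3")
  }
  if (!is.null(tsv_path)) {
    out <- data.frame(family = tr$family, gene = tr$gene_id,
                      contig = tr$contig, frame = tr$frame,
                      start = tr$start, end = tr$end,
                      intron_region = ifelse(is.na(tr$intron_region), ".",
                                             tr$intron_region),
                      intron_length = ifelse(is.na(tr$intron_length), ".",
                                             tr$intron_length),
                      note = ".", stringsAsFactors = FALSE)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(gff = gff_path, tsv = tsv_path))
}
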