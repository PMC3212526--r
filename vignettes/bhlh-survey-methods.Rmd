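---
title: "Methods: a genome-wide bHLH transcription-factor census"
author: "bhlhcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide bHLH transcription-factor census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhlhcensus)
```

## The problem

Basic helix-loop-helix (bHLH) proteins form one of the largest transcription
factor superfamilies in animals. The diagnostic bHLH domain is roughly 60
residues: a DNA-binding basic region, two amphipathic helices, and a variable
loop between them. Animal bHLH proteins are conventionally organised into 45
families, grouped into six higher-order groups A-F by target DNA element and
domain architecture (group A holds 22 families, B 12, C 7, D 1, E 2, F 1; the
packaged catalog `census_fixture("family_groups.tsv")` records this mapping).

A genome-wide census of this superfamily for a newly sequenced genome
answers: how many bHLH members does the genome encode, which family is each
member orthologous to, and how are the motifs laid out on the genome
(including introns interrupting the motif itself)? `bhlhcensus` implements
this census as a reusable pipeline:

1. **motif search** - translated six-frame scanning of genomic contigs with a
   set of reference bHLH motifs, with chaining of sub-hits across
   intron-sized gaps and deduplication of hits sharing contig, reading frame
   and coding regions;
2. **conserved-site filter** - a two-stage rule over 19 canonical conserved
   alignment positions that separates genuine bHLH motifs from chance hits;
3. **orthology calling** - per-candidate in-group phylogenetic analysis
   (candidate + related reference members + a distant outgroup) under three
   tree methods with bootstrap, and a four-way outcome categorization;
4. **intron analysis** - intron lengths and motif sub-region locations from
   genomic coding segments;
5. **reporting** - family/group member counts, annotation audits, intron
   summaries.

A synthetic-genome generator with exact ground truth makes every stage
testable offline, and transcriptions of a published giant-panda survey (107
members, 44 families) are shipped as plain-text fixtures that the same
reporting code consumes.

## Motif search

The search replaces a tblastn screen with an in-package equivalent built on
`Biostrings::pairwiseAlignment`:

* every reference motif is locally aligned against all six translation
  frames of each contig (one batched alignment call per frame; codons with
  ambiguity characters translate as X and never count as matches);
* sub-hits above `piece_threshold` are trimmed to their high-confidence
  cores (terminal residues up to the first strong match are dropped, because
  local alignments routinely over-extend a few residues into intron
  translation on chance matches);
* cores on the same strand are chained by dynamic programming when their
  query intervals are compatible and the genomic gap is at most `max_gap_bp`
  (default 50 kb, chosen to cover the longest published motif intron of
  45,217 bp); each junction costs `junction_penalty` so isolated noise
  sub-hits cannot buy their way into a chain;
* query stretches still missing from a chain are *rescued*: the
  exactly-missing residues are slid along the translated gap window
  (ungapped positional scan in all three frames) and the best placement is
  accepted when it is flanked by splice signals (`AG` before, `GT` after, as
  applicable);
* finally, exon boundaries are refined so that each intron carries `GT..AG`
  terminal dinucleotides, choosing among compatible boundary placements by
  the translation score of the spliced product, and terminal segments whose
  junction shows no splice signal are dropped as chaining artifacts.

The rescue and refinement stages are this package's stand-in for the manual
curation steps of published surveys (completing intron-interrupted hits and
locating splice junctions by hand). The hit score threshold is deliberately
permissive - the original surveys ran their screens at E = 10 precisely so
that the conserved-site filter, not the search, decides membership.

Coordinates follow the published table conventions throughout: 1-based,
inclusive, with minus-strand segments recorded in descending (reading)
order, and frames labelled +1..+3 / -1..-3 by offset from the contig start
and end respectively.

## Conserved-site filter

Candidates are aligned to the reference consensus (global alignment with
free end gaps; the contract is the downstream site evaluation, not the exact
alignment string, so the gap penalties are plain configuration) and scored
at 19 conserved positions. The canonical positions are an alignment
convention rather than a printed fact, so they are configuration with a
documented default: 19 strictly increasing positions on the 60-column
profile, including the two most conserved motif sites (23 and 59), weighted
toward the basic region and helix 2 and away from the variable loop. A
site's "conserved set" is every residue reaching the `cutoff` frequency
(default 0.5) among the references.

The filter then applies the published two-stage rule literally: candidates
with fewer than nine variations are potential members (stage 1), and
candidates with fewer than ten conserved residues are discarded (stage 2).
The two thresholds are not complementary - variations < 9 already implies
matches >= 11 - and the package keeps both stages as written, reporting in
the `stage` column which rule caught each discarded candidate rather than
silently merging them.

Accepted candidates get a total basic/helix1/loop/helix2 region map by
carrying the 60-column region template through the alignment; inserted
residues inherit the region of the preceding aligned column, so the four
intervals stay contiguous and cover the candidate.

## Phylogenetic engine

Four pieces, all deterministic given their seeds:

* **Distances.** The step-matrix distance between aligned motifs is the mean
  per-column cost over columns where both sequences carry a standard
  residue. The cost table derives from the Dayhoff PAM250 log-odds matrix as
  `cost(a,b) = S(a,a) + S(b,b) - 2 S(a,b)` - integer, symmetric, zero
  diagonal - standing in for the historical PAUP-format PAM250 step-matrix
  files, which are no longer retrievable.
* **Neighbor joining**, written in-package with a smallest-index tie-break
  so results are reproducible; negative branch lengths are clamped to zero.
  On additive matrices NJ provably recovers the generating tree, and the
  test suite checks this exactly against `ape`'s independent implementation.
* **Maximum parsimony** by exact search: exhaustive enumeration of all
  unrooted topologies up to 8 taxa (10,395 at n = 8), branch and bound with
  the partial-tree Fitch length as lower bound up to 12. Fitch lengths use a
  20-bit state encoding, and per-site cost vectors over the enumerated
  topologies turn the bootstrap into a single matrix product per replicate.
  Ties resolve to the first optimum in a fixed enumeration order.
* **Bootstrap** by column resampling with a stated seed; support for an
  internal edge is the percentage of replicate trees containing the same
  bipartition.

The published procedure's third method, quartet-puzzling maximum likelihood,
is not reimplemented. In its place the package uses an **ML-surrogate**:
neighbor joining over maximum-likelihood JTT pairwise distances
(`phangorn::dist.ml`), bootstrapped like the other methods (default 100
replicates, playing the role that puzzling-step support percentages play in
the original). The orthology caller only needs, per method, a reference tree
plus bipartition supports, so any 2-3 methods can be supplied. For small
in-groups the decision procedure - not the specific ML optimizer - carries
the scientific content, which is why this substitution is acceptable; it is
also why bootstrap integers from published tables are not expected to be
reproduced digit-for-digit by any reimplementation.

## Orthology calling

For each candidate, the global NJ tree over all candidates, all references
and the outgroup guides in-group selection: the smallest outgroup-rooted
clade around the candidate holding at least `min_refs` references (default
4, so the in-group usually spans two families), capped at `max_refs = 6` by
patristic proximity. Keeping the in-group at eight taxa or fewer (candidate
+ 6 references + outgroup) means maximum parsimony runs as an exact
all-topology evaluation even inside the bootstrap.

Per method, the candidate's **partner** is the unique reference forming a
two-taxon clade with it in the outgroup-rooted tree, with the bootstrap
support of that clade; failing a partner, the candidate is `n/m*` when it is
monophyletic with all present members of some family, and `n/m` otherwise
(the published table's notation). With S = the number of methods supporting
the same partner with bootstrap strictly above 50 ("exceed 50" is read
strictly, so a support of exactly 50 counts as weak):

| S | category | meaning |
|---|----------|---------|
| 3 | 1 | all methods agree with strong support |
| 2 | 2 | two methods strong, one weak or non-monophyletic |
| < 2, partner found | 3 | orthology assigned on thin support |
| no partner anywhere | 4 | whole-protein fallback |

Category 4 triggers a rerun with whole-protein sequences when they are
supplied; any partner found then is recorded as category 4, mirroring the
published handling of the four members whose motifs alone would not resolve.
Because the boundary is strict, one published row with a support of exactly
50 classifies as category 3 here although the original prose counts it in
its second group; the package documents rather than hides this reading. The
categorization is total (every result triple maps to exactly one category)
and monotone (raising a support value never demotes a candidate).

## Intron analysis

The intron between consecutive reading-order coding segments has length
`|downstream_start - upstream_end| - 1`, identically on both strands, and is
located in the motif sub-region holding the residue whose codon it
interrupts; an intron falling exactly between codons takes the downstream
residue's region (a deterministic tie-break consistent with single-region
labels in published tables).

The packaged coding-region table is transcribed verbatim from the published
record. Validation recomputes every printed intron length from the printed
coordinates; eight intron rows and four segment rows are internally
inconsistent in the source text (digit-level corruption - for example one
236 bp intron is exact if a single digit of the neighboring segment start is
restored) and are carried on a documented skip-list,
`table2_anomalies()`. The printed intron lengths remain authoritative for
the survey statistics: the published mean of 4,393 bp is exactly the mean of
the 70 printed lengths. Members split over two contigs yield no intron and
keep their printed note.

## The synthetic test bed

`synthetic_reference_set()` builds a catalog stand-in: 15 families spread
over groups A-F in the animal-catalog proportions, each family a prototype
mutated from a fixed 60-residue bHLH consensus at non-conserved sites (rate
0.35), members mutated from the prototype at rate 0.25. These rates put
within-family motif identity near 60-85% and between-family identity lower,
matching the divergence regime in which published in-group analyses resolve
orthologs at high bootstrap. The 19 conserved sites are never mutated, so
every reference and every planted gene passes the conserved-site filter by
construction - which is the point: the generator tests the pipeline's
recovery, not the biology of site conservation.

`generate_genome()` plants genes one per contig: a family member is mutated
at `sub_rate` (default 0.05, conserved sites protected), reverse-translated
with a fixed most-frequent-codon table, split by 0-3 introns (counts drawn
with probabilities 0.56/0.24/0.18/0.02, the 60/26/19/2 proportions of the
published survey; lengths log-normal, meanlog 7, sdlog 1.3, clamped to
[60 bp, 45,217 bp]), placed on a random strand inside i.i.d. background of
GC 0.42, plus one background-only decoy contig. Introns start `GT` and end
`AG`; the 60 bp minimum keeps splice signals from colliding with coding
sequence. Intron codon positions keep every exon at eight or more codons
(edges and between introns) so each exon carries enough alignment signal to
clear the scanner's sub-hit floor; real tables contain 1-3 codon terminal
exons, which published surveys completed by hand and which this generator
deliberately does not emulate.

What passing on this test bed does and does not show: the generator has no
repeats, no paralog clusters, no pseudogenes, no sequencing error and no
non-canonical splice sites, so recovery rates here are upper bounds for real
genomes; what the tests do establish is that the survey logic - chaining,
filtering, in-group decision procedure, intron arithmetic, aggregation - is
implemented correctly against a known truth.

Problem sizes used by the packaged validation runs: recovery is measured on
20-gene genomes over seeds 1-10 with in-group bootstraps of 200 (NJ), 100
(MP) and 100 (ML-surrogate); the full-scale defaults (NJ 1,000 / MP 100)
remain the package defaults for real analyses. With these conditions,
essentially all planted genes are detected and assigned to the correct
family at category 1-2; exact recovery of every intron boundary additionally
requires every splice junction to be reconstructed bp-exactly and lands
around 98-99% of genes, the residual being weak small exons whose boundary
evidence is genuinely ambiguous even to a human curator.

## Numerical and design choices

* Consensus cutoff 0.5 for conserved sets; modal-residue fallback keeps the
  sets non-empty.
* NJ tie-break: smallest index pair; MP tie-break: first optimum in
  enumeration order; both documented and deterministic.
* Bootstrap seeds: each method derives its stream from the caller's seed;
  reruns are bit-identical.
* Degenerate inputs: all-gap sequence pairs, empty reference FASTAs, empty
  intron tables, single-segment and multi-contig gene structures all have
  defined behavior covered by tests.
* The two filter thresholds are kept as two sequential stages exactly as
  published, with the redundancy surfaced rather than merged.
* Candidate labels are kept Newick-safe by construction.

## Known limitations

* The scanner assumes substitution-dominated divergence between query and
  target motifs; large indels inside exons defeat the gapless core/rescue
  machinery (heavier gap penalties are deliberate, to stop balanced-indel
  chimeras across introns).
* Exons shorter than ~4 codons at the motif edges are not reliably
  recoverable without manual curation; the generator documents and avoids
  this regime.
* The ML-surrogate is not quartet-puzzling ML; its supports are comparable
  in role, not in value.
* The in-group cap of 6 references trades a little selection breadth for
  exact MP inside the bootstrap; raising it past 8 taxa switches MP to
  branch and bound per replicate, which is markedly slower.
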