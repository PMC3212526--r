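# bhlhcensus

Genome-wide censuses of basic helix-loop-helix (bHLH) transcription factors,
as an R package. The bHLH domain is a ~60-residue DNA-binding/dimerization
motif (basic region, helix 1, loop, helix 2); animal bHLH proteins fall into
45 families organised into six higher-order groups A–F. Given unannotated
genomic contigs and a reference motif catalog, `bhlhcensus` finds candidate
bHLH motifs by translated six-frame scanning with intron-aware segment
chaining, validates them with a two-stage filter over 19 conserved alignment
sites (keep candidates with fewer than nine variations; discard candidates
with fewer than ten conserved residues), assigns each survivor to a family by
in-group phylogenetic analysis — neighbor joining on a PAM250-derived step
matrix, exact branch-and-bound maximum parsimony, and an ML-surrogate over
JTT maximum-likelihood distances, each bootstrapped, with a monophyly-based
partner test and a four-way outcome categorization — and derives intron
lengths and motif sub-region locations from the genomic coding segments
(`intron = |downstream_start − upstream_end| − 1`).

The package is aimed at comparative genomicists cataloguing a transcription
factor superfamily in a newly sequenced genome. Everything runs offline: a
synthetic-genome generator plants family-labelled, intron-split bHLH genes
with exact ground truth, and plain-text transcriptions of a published
giant-panda bHLH survey (107 members over 44 families) ship as fixtures.

## Worked example

Reproduce a published survey's statistics from the packaged tables:

```r
library(bhlhcensus)
rep <- fixture_report()
rep
#> bHLH survey report
#>   members: 107 | families: 44
#>   per group: A=46 B=25 C=15 D=4 E=11 F=3 orphan=3
#> Intron summary over 107 members:
#>   members with motif introns: 47
#>   intron-count histogram (1/2/3): 26/19/2
#>   total introns: 70 | longest: 45217 bp | mean: 4393 bp
#>   annotations: 54 agree, 37 differ, 13 hypothetical
```

107 members mapped through the family→group catalog give 46/25/15/4/11/3
members in groups A–F plus 3 orphans; 47 members carry introns inside the
motif itself (70 introns in all, longest 45,217 bp, mean 4,393 bp); 13
database annotations were mere "hypothetical protein" entries that the
survey identifies as bHLH members.

And a full pipeline run against planted ground truth:

```r
res <- run_synthetic_pipeline(n_genes = 10, seed = 1)
res$recovery[1:3, ]
#>    gene_id   family detected family_correct category introns_exact
#> 1 synth001 SynFam05     TRUE           TRUE        1          TRUE
#> 2 synth002 SynFam06     TRUE           TRUE        1          TRUE
#> 3 synth003 SynFam15     TRUE           TRUE        1          TRUE
```

Each planted gene is scanned, filtered, phylogenetically assigned
(`category` 1 = all three methods support the same partner with bootstrap
above 50), and its introns re-derived from the recovered coding segments.

The methods vignette (`vignettes/bhlh-survey-methods.Rmd`) documents the
models, thresholds, tie-breaks and the generator's assumptions.

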