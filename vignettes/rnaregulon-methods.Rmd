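---
title: "Methods: reconstructing RNA motif regulons by comparative genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing RNA motif regulons by comparative genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaregulon)
```

## The reconstruction model

`rnaregulon` reconstructs regulons controlled by *cis*-regulatory RNA motifs
(riboswitches, PyrR sites, ribosomal and amino acid operon leaders,
T-boxes) from three inputs: per-genome gene annotations, covariance-model
hit tables for the motif families, and a gene-to-ortholog-group map. The
method rests on two biological assumptions. First, RNA regulatory elements
act in *cis* on the operon immediately downstream, so a motif hit can be
attributed to a target operon purely by position and strand. Second, a
genuine regulatory interaction is conserved across related genomes, so
clustering candidate targets by orthology and scoring their conservation
separates real regulon members from spurious covariance-model hits; this
cross-genome filter is what keeps the overprediction rate down.

The pipeline stages are pure functions of their inputs: import → operon
inference → site assignment → CRON clustering and acceptance → optional
T-box specificity splitting → functional classification → statistics. Each
stage reads and writes plain tables, so any stage can be rerun or replaced.

## Stage definitions and parameters

**Operon inference** (`infer_operons`). Genes on one contig are scanned in
genomic order; a gene joins the current operon when it lies on the same
strand and either the intergenic gap is at most `max_gap` (default 200 nt)
or its coding region overlaps the operon (the coding-overlap option, on by
default). The gap is defined as `next.start − prev.end − 1`, the number of
nucleotides strictly between coding regions, measured against the running
maximum end so that nested genes cannot reopen a boundary; this makes the
200 nt bound inclusive and exactly testable (a 200 nt gap merges, 201
breaks). Strand changes always break operons. Whether the source procedure
treated 200 nt as inclusive is not documented; the inclusive reading is the
package's choice. Within an operon, genes are ordered 5′→3′ in transcription
direction; the first gene is the leader anchor.

**Site assignment** (`assign_sites`, `deduplicate_hits`). Hits below their
family's score threshold (the registry's per-family noise cutoff) are
dropped at import. Overlapping hits of one family (same genome, contig and
strand) are deduplicated greedily by descending score, ties broken by
leftmost start then site id. Deduplication is restricted to one strand
because overlapping opposite-strand hits describe different molecules. A
site is assigned to an operon when its *gene-proximal end* — the
coordinate nearest the start codon in gene orientation — lies between
`upstream` (default 500 nt) before and `downstream` (default 100 nt) after
the leader's translation start. The proximal end is used because riboswitch
aptamers abut the regulated reading frame; which coordinate the original
procedure measured is not documented, and the proximal end is the
reproducible choice. A site qualifying for two operons (divergent
promoters) goes to the nearer start codon; an exact distance tie leaves it
unassigned and flagged for curation rather than guessed. Two or more
same-family sites on one operon form a single regulated operon with a
tandem flag — no extra spacing cap is imposed beyond the window, the
simplest rule consistent with tandem glycine riboswitch arrangements.

**CRON clustering** (`build_crons`, `score_conservation`, `accept_crons`,
`extend_operons`). Within one taxonomic group and motif family, regulated
operons are first clustered by the ortholog group of their leader gene;
cluster pairs whose member-operon ortholog sets have Jaccard index ≥ 0.5
are then merged as connected components. The interactive clustering this
replaces was never published in algorithmic form; anchor-first grouping
with single-linkage Jaccard merging is the simplest reproducible reading,
and the merge predicate is checked against a brute-force transitive-closure
oracle in the tests. A merged CRON's anchor is the most frequent leader
ortholog group (ties lexicographic). Conservation is the fraction of
*anchor-bearing* genomes that are regulated; counting only anchor-bearing
genomes means gene absence (e.g. auxotrophy) does not penalize regulatory
conservation. Acceptance — conservation ≥ 0.5 in ≥ 2 genomes, with a
rescue for single-genome CRONs whose best site reaches the family's
high-confidence score threshold — replaces curator judgment and is
deliberately configuration, not constants. Accepted operons are extended by
the next same-strand downstream gene when its gap is ≤ 300 nt and its
ortholog group occurs in at least half of the other member operons,
iterated to fixpoint; extension deliberately overrides the initial operon
partition for accepted CRONs only.

**T-box specificity** (`call_specificity`, `split_tbox_regulogs`). The
specifier codon is located by reference anchoring: a declared reference row
and three ungapped reference positions are mapped to alignment columns, and
each row's characters at those columns form its codon. This replaces visual
inspection of alignments with a reproducible equivalent and is invariant to
all-gap column insertion and row order. Codons containing gaps or
ambiguity, and stop codons, are reported unresolved rather than imputed.
Resolved codons translate by the standard genetic code (RNA alphabet); all
synonymous codons of an amino acid share one specificity group, so the
group inventory (e.g. 18 groups in a community) is an observation, not a
parameter. Lineage-level T-box regulogs are replaced by one regulog per
specificity group present; unresolved operons go to an excluded
"unassigned" bucket, and the accounting identity
`total − lineage-level T-box + specificity-level` is exposed as
`regulog_accounting()`.

**Functional classification** (`assign_categories`). Roles map to 45
Specific Functional Categories nested in 10 Overall Functional Categories
via a bundled, user-editable table; the scheme is data, not code. Matching
is exact after case/whitespace normalization — fuzzy matching would
silently reclassify genes, whereas unmapped roles are visible in the
Miscellaneous fallback.

**Statistics** (`lineage_stats`, `motif_stats`, `ofc_proportions`,
`tandem_stats`, `classify_distribution_group`). Distribution classes fix
ribosomal leaders, amino acid leaders and T-boxes to groups D, E, F; other
motifs are A when present in more than 75% of taxonomic groups, C when
present in at most three, otherwise B. Summary ratios follow a mixed
formatting rule: half-up rounding, integers at 10 and above, one decimal
below (so 39 sites/genome but 7.6). The grand summary row uses two
different averaging conventions on purpose — sites per genome is the
weighted ratio of grand totals, genes per genome the unweighted mean of
lineage ratios — because the reference table this reproduces mixes the two;
both conventions are labeled in the output's `convention` attribute.
OFC proportions exclude genes in the "Other or unknown functional roles"
SFC before normalizing (the other Miscellaneous SFCs participate); scopes
with no classified genes are labeled `N/A`. Degenerate inputs (zero
genomes, zero sites, no regulated operons) yield zeros or flagged `NA`s,
never division errors.

## The synthetic community

`simulate_community()` generates what the method assumes about real data:
taxonomic groups of genomes sharing ortholog groups, group-level operon
blocks instantiated per genome (filler groups present with probability
0.9), planted regulons whose sites sit strictly inside the assignment
window of their operon leader, spurious sites in intergenic positions
strictly outside every (padded) window, tandem arrangements, and
template-generated T-box alignments with known specifier codons. Drawn
intra-operon gaps (20–150 nt) sit inside the 200 nt merge bound and
inter-operon gaps (300–900 nt) outside it, so the planted operon structure
is exactly recoverable and ground truth is unambiguous. Each anchor-bearing
genome is regulated independently with the configured conservation
probability, so empirical conservation is binomial around the configured
level (a property the tests check). Gene *sequences* are not generated —
coordinates and roles suffice for every stage except T-box alignments,
which are template-generated.

Default study conditions: the glycine-like regulon uses tandem probability
0.82 and a 1–4 gene operon-size distribution with mean 2.3, the
characteristic glycine riboswitch profile; the recovery benchmark
(`recovery_config`) plants five riboswitch regulons per group at
conservation 0.8 across two groups of five genomes with one spurious site
per genome (≈20% of emitted sites). Problem sizes (60 genes per genome,
2×4 or 2×5 genomes, 20 recovery replicates, 10 glycine replicates) were
chosen once as the smallest community in which every phenomenon of
interest — paralogy, strand mixtures, divergent windows, conservation
sampling — actually occurs.

What passing tests do *not* show about real data: spurious sites are placed
outside windows by construction, so the benchmark's precision measures the
window/conservation logic, not robustness to covariance-model hits that
land inside true regulatory regions; gene lengths and gaps are uniform,
not genome-realistic; orthology is error-free; and functional roles are
exact strings, whereas real annotations require curation before they match
a category table.

## Known limitations

- CRON acceptance replaces per-CRON curator decisions with global
  thresholds; borderline CRONs that a curator would accept on genomic
  context will be rejected, and vice versa.
- The regulatory region is not expanded beyond the fixed window, and
  transcription- versus translation-level mechanisms are not
  distinguished.
- Orthology is consumed as given; paralog mis-grouping propagates into
  CRON anchors.
- The bundled category table covers the published category names; real
  annotation pipelines need their role vocabulary mapped onto it.
- Running covariance-model searches, sequence-similarity annotation and
  database upload are out of scope by design: hits and roles are inputs.
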