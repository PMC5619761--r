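---
title: "Methods: a reproducible census pipeline for plant GRAS transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reproducible census pipeline for plant GRAS transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grascensus)
```

## The problem

GRAS proteins are a plant-specific transcription-factor family (named for
GAI, RGA and SCR) with a conserved C-terminal domain built from five ordered
blocks — LHRI, VHIID, LHRII, PFYRE and SAW — and a variable N-terminus.
Genome-wide censuses of the family follow a well-worn recipe: nominate
candidate proteins by a profile-HMM search against the proteome, collapse
splice variants to gene loci, characterize each representative protein
(length, molecular weight, isoelectric point, chromosome location), build a
distance-based phylogeny to assign subfamilies against reference-species
anchors, call duplicate gene pairs by alignment coverage and identity
criteria, summarize exon–intron structure and conserved-motif content, and
relate all of it to tissue expression. `grascensus` packages that recipe as
tested, reusable functions, together with a planted-truth synthetic-genome
generator so that every stage can be validated offline, without downloading
a proteome or an expression atlas.

The package ships one real data set: the published 86-row characterization
table of the maize GRAS family (`table1_fixture()`), used to reproduce the
census summary statistics exactly.

## Family nomination and the census

Candidates are proteins with at least one domain hit whose full-sequence
E-value is at or below the cutoff (default `1e-5`). The comparison is
inclusive (`<=`): HMMER-style tools report pass-at-threshold as "at or
below", and the choice only matters for hits exactly on the boundary.

Splice variants are collapsed by gene locus (derived from the sequence
identifier by a configurable suffix rule, e.g. `GRMZM2G015080_P01` →
`GRMZM2G015080`). The representative isoform is the longest protein, with
ties broken by the lexicographically smallest protein id; this is the
standard choice for family censuses, and the number of member isoforms is
kept as `n_splice_forms`. Census entries are numbered in ascending locus
order, which makes the naming deterministic and reproduces the convention
of numbering family members by locus id.

Molecular weight is the sum of average (isotope-averaged) residue masses
plus one water, 18.01524 Da. The isoelectric point is the root of the
Henderson–Hasselbalch net-charge model over the ionizable groups
(N-terminus, K, R, H as bases; C-terminus, D, E, C, Y as acids) found by
bisection on pH 0–14 to `|charge| < 1e-4`. The pKa set defaults to
EMBOSS-style values and is configurable; published pI values depend on the
(unstated) tool and pKa table a study used, so exact third-party pI values
are not a validation surface — the packaged census table carries the
published values as data instead. Proteins containing the ambiguity code
`X` keep their census row but get `NA` weight and pI with a warning, since
`X` has neither a defined mass nor a defined charge.

A documented quirk of the published table this package mirrors: its
molecular-weight column is headed "kDa" but holds values in Daltons
(e.g. 55337.9). The fixture stores Daltons as printed and does not guess at
the original intent. The published text and table also disagree on the
maxima (734 vs 809 aa; pI 7.7965 vs 10.717); the package computes from the
table, and the summary statistics reproduce the table's values. For the
same reason the printed mean pI (6.44532) is treated as soft: recomputing
over the 86 printed rows gives 6.45290.

## Phylogeny and subfamily assignment

Distances are uncorrected p-distances — mismatches over columns where both
sequences carry a residue, gap columns excluded pairwise — computed either
on a supplied alignment (`msa_pdist`) or from pairwise global alignments.
The Kimura protein correction (`-ln(1 - p - 0.2 p²)`, ceiling beyond
p = 0.854) is opt-in, because the upstream tools whose behaviour this
emulates do not state their correction and the subfamily assignment is
rank-based, not scale-based.

Trees are built by canonical neighbor joining. Two numerical choices are
pinned down for determinism: ties in the Q criterion are broken by the
lexicographically smallest label pair, and a negative branch length at a
join is clamped to zero with the deficit moved to its sibling edge
(PHYLIP-compatible). On any additive matrix NJ provably recovers the
generating topology; the test suite checks this against a brute-force
least-squares oracle (all unrooted topologies enumerated and OLS-fitted)
for up to 6 taxa, and by the zero-residual certificate — only the true
topology can fit an additive matrix with zero residual — for 7–8 taxa,
where enumeration (10,395 topologies at n = 8) would dominate the test
budget for no extra rigor.

Bootstrap supports resample alignment columns with replacement; replicate
`r` seeds the RNG with `seed + r`, so runs are reproducible and could be
parallelized without changing results. Support is the percentage of
replicates containing the same bipartition, as an integer node label.

Subfamily assignment midpoint-roots the tree (the emulated study presents a
rooted-looking tree without stating a rooting rule; midpoint is the
assumption-free default), then labels each query by the majority anchor
label in the smallest clade strictly below the root containing the query
and at least one anchor. Ties and anchor-free paths yield `UNASSIGNED`;
the function can never invent a label absent from the anchor set.

## Duplication criteria

A pair of genes is a candidate duplication event when the global protein
alignment (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5 — the
emulated study names no aligner, so conventional defaults are used and
configurable) satisfies both criteria *strictly*: aligned-region identity
> 80% and coverage > 80% of the longer protein. Coverage is defined as
both-residue columns over the longer input length, interpreting "covers the
longest gene" at the protein level. Because coverage can never exceed the
length ratio of the pair, pairs whose ratio is already at or below the
threshold are skipped before alignment — an optimization the property tests
verify cannot change results.

"Tightly linked" genes contribute one event. Linkage is chained gap-wise:
genes on one chromosome whose spans lie within 200 kb (configurable) form a
group, and among passing pairs inside one group (or one unordered pair of
groups) only the highest-identity pair is kept. The intervening-gene
criterion (≤ 5 annotated genes between the pair) is used for
tandem/segmental classification but deliberately *not* for grouping: among
family genes alone every consecutive pair has zero intervening members, so
that criterion would chain entire chromosomes into single groups.

## Structure, motifs, expression, qPCR

Intron counts are exons minus one on the representative transcript — the
same longest-protein isoform the census chose, keeping the structure panel
consistent with the census. Motif occurrences are consumed as a table (the
de novo motif discovery a study would run with MEME is out of scope; the
contribution here is downstream). A motif is subfamily-specific when its
presence rate is ≥ 0.7 inside and ≤ 0.2 outside the subfamily; these two
thresholds are invented defaults — the emulated analysis asserts
specificity only qualitatively — and are exposed as arguments.

Expression rows can be z-scored or max-scaled; constant rows map to zeros
rather than NaN. Clustering is agglomerative with centered Pearson distance
(`1 - r`) or Euclidean distance and average/complete/single linkage,
computed with pairwise-complete observations; genes observed in fewer than
half the tissues are excluded with a warning, and exact merge-distance ties
break toward the leftmost original row so dendrograms are identical across
platforms. Duplicate-pair expression similarity is Pearson `r ≥ 0.8` across
tissues, `undeterminable` below 3 shared observed tissues.

Comparative-Ct quantification averages Ct replicates per (sample, gene)
first, then forms `dCt = Ct(target) - Ct(reference)`,
`ddCt = dCt(sample) - dCt(calibrator)` and returns `2^-ddCt`; per-replicate
values (each target replicate against the mean reference Ct) are returned
separately for error bars. Averaging first (rather than averaging
per-replicate ratios) is the stated design choice; the two differ only by
Jensen-gap terms at realistic noise.

## The synthetic genome

`synthetic_family_spec()` defaults *are* the study conditions the package
emulates: 86 genes over 8 subfamilies (SCL3/HAM/DELLA/SHR/PAT1 = 10 each,
LS/SCR = 4, LISCL = 28, matching the reported subfamily sizes), 11 planted
duplicate pairs (3 tandem, 8 segmental, echoing the reported predominance
of segmental events) of which 9 share expression patterns (the published
9/11 = 81.82% proportion), 80% intronless genes with the 1–5 intron tail
weighted as reported (9:5:2:0:1), 10 chromosomes, 13 tissues, 18 loci with
an extra splice form (104 transcripts → 86 loci), 40 decoy proteins and 2
anchors per subfamily.

Each protein is a subfamily-specific 120-aa N-terminal block plus shared
C-terminal blocks (LHRI 30, VHIID 30, LHRII 30, PFYRE 40, SAW 40 aa)
diverged per subfamily at 10% per site; per-gene substitutions are
calibrated as `1 - sqrt(background_max_identity)` so unrelated
same-subfamily proteins sit near the 0.5 background identity ceiling, far
below the 0.8 duplication threshold. Duplicates are copies substituted at
`1 - 0.92` of sites (no indels, keeping the planted identity analytic — the
realized alignment identity lands within ±0.03 of target). Intergenic gaps
are drawn log-uniform from 250 kb–2 Mb, a floor above the 200 kb tandem
window, while tandem partners sit 5–50 kb apart — so exactly the planted
tandems are tightly linked. Decoy E-values are drawn log-uniform in
[1e-4, 1] and member E-values in [1e-30, 1e-6], unambiguously separated at
the 1e-5 cutoff; threshold-boundary behaviour is exercised by explicit
fixtures instead. Expression archetypes give each subfamily three
high-expression tissues; dissimilar duplicate partners get private
archetypes, and one non-duplicate gene carries an exact planted fold
(default 4×) between one tissue and the calibrator so comparative-Ct
recovery has a closed-form truth. Ct values follow
`Ct = 28 - log2(expr) + N(0, 0.15)` with triplicates and a constant
reference gene (`ACTIN`, CV < 2% by construction).

What the generator does *not* emulate: indels, codon structure, rate
heterogeneity, genuine evolutionary history, microarray normalization
artifacts, or missing data patterns of a real expression atlas. Passing
recoveries therefore demonstrate that the pipeline's logic implements its
stated criteria correctly — not that those criteria are robust to the
messiness of real proteomes, where alignment ambiguity and fragmentary gene
models blur the planted separations.

Because all sequences are built from fixed-length blocks, family proteins
are equal-length and serve directly as the "precomputed alignment" the
phylogeny stage expects; with real data a multiple alignment must be
supplied (alignment itself is a non-goal).

## Problem sizes and reproducibility

The test suite and the acceptance script run the full default genome (86
genes, 104 transcripts, 40 decoys), a 200-matrix NJ validation over 4–8
taxa, and a 500-pair alignment-score validation against an independent
dynamic-programming recomputation; these sizes keep the complete validation
under a few minutes on one core while leaving each check statistically
meaningful. Every stochastic step takes an explicit integer seed;
`generate_family()` seeds with `seed`, `generate_expression()` with
`seed + 1`, and bootstrap replicate `r` with `seed + r`. Regenerating with
the same spec and seed is bit-for-bit identical, and `run_pipeline()`
records config, seed and input checksums in a manifest that suffices to
reproduce a run.

## Known limitations

* Subfamily assignment depends on anchor quality; with a single divergent
  anchor per subfamily the majority rule degenerates to nearest-anchor.
* The duplication scan is all-pairs; for proteomes far larger than a
  family census it would need a pre-clustering step.
* `pairwise_global` distance mode aligns every pair and is quadratic in
  family size; it is intended for unaligned inputs of modest size.
* The comparative-Ct model assumes perfect (2-fold per cycle)
  amplification efficiency, as the emulated protocol validated primers by
  melting curve only.
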