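---
title: "cotscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cotscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fly and worm RNAi screens silence genes with long (300–800 bp) dsRNAs that
DICER cuts into many ~21-nt siRNAs. Each siRNA can silence not only the
intended gene but any gene it aligns to with few mismatches. The standard
control — repeating the experiment with a second, non-overlapping dsRNA from
the same gene — fails silently when siRNAs from *both* dsRNAs happen to hit
the *same* off-target gene: the shared phenotype then looks on-target.
`cotscan` quantifies this risk and designs dsRNA region pairs for which it
cannot occur, at the level of sequence similarity.

The central object is the **cot-group** (common off-target group): two or
more siRNAs derived from one source gene that all map, with at most *k*
mismatches over their full length *L*, to the same off-target gene. Defaults
are *L* = 21 and *k* = 3, gapless alignments only.

## The seed-table search

All candidate alignments are found with an exact seed-and-join algorithm:

1. A **seed table** is built over the target space with word size *w* = 9.
   Its key space is exactly $4^9 = 262{,}144$ words; for every word it holds
   the complete, sorted list of occurrence locations (record, offset). Words
   containing N are not indexed — an ambiguous base can never match under
   Hamming semantics, so every window containing N is excluded from both
   engines by definition.
2. A query of length *L* is tiled into $\lfloor L/w \rfloor$ contiguous
   9-nt children plus a remainder (21 = 9 + 9 + 3). For a hit with
   $m \le k$ total mismatches, the children carry $i$ and $j$ of them with
   $i + j \le k$. Looking up every Hamming variant of child 1 at exact
   distances $0..k$ and of child 2 likewise, and joining locations that sit
   exactly 9 nt apart, therefore generates a superset of all true hits —
   no alignment can escape the enumeration.
3. Each joined candidate locus is verified once by direct comparison, which
   settles the 3-nt remainder and the exact mismatch count, and removes
   candidates reached through several $(i, j)$ budget splits. The paper-style
   formulation avoids any string comparison for an 18-nt query (two exact
   children); at *L* = 21 a remainder check is unavoidable, and verifying the
   full window at the candidate locus is the cheapest sound way to do it.

Variant enumeration is arithmetic, not string-based: a word is held as
base-4 digits, the key deltas of all single-position substitutions form a
$9 \times 3$ matrix, and which (position, substitution) tuples make up an
exact-distance-$d$ shell is independent of the word, so those index tables
are precomputed once. The shell sizes are $\binom{9}{d} 3^d$: 27, 324 and
2268 for $d$ = 1, 2, 3.

Only the sense strand of each target record is indexed; the reverse
complement of the query is searched as a second orientation. This halves the
index for an equivalent contract, and is the right shape for siRNA work — a
dsRNA produces siRNAs of both polarities, so both orientations are always
searched and reported.

The package also ships `naive_search()`, a position-by-position Hamming scan
over the concatenated target space (inner loop in C). It shares no machinery
with the seed-table engine and is used throughout the tests — together with
an independent Biostrings `matchPattern()` cross-check — to assert that the
two engines return byte-identical hit sets.

## Target spaces: pre-mRNA and mature mode

Off-targeting can occur on unspliced transcripts, so the default target
space (`premrna` mode) is one record per gene: the strand-corrected genomic
span, with every position labelled exon or intron. `mature` mode indexes the
spliced transcript instead, labelled UTR5/CDS/UTR3. A hit window in premrna
mode is classified `exon` only if **all** its positions are exonic; windows
straddling an exon/intron boundary count as intron, because no mature RNA
contains such a window — this makes `filter_intron_hits()` consistent with
what mature transcripts can present.

For multi-isoform genes the longest mature transcript is analysed by
default; a specific transcript ID can be requested. This is a policy choice:
when a "cDNA" is named without an isoform, the longest transcript is the
most inclusive single-molecule reading. Gene identity for hit aggregation is
always the annotation's gene ID, so hits to any record of a gene count as
hits to that gene.

## siRNA enumeration and the activity filter

Every start position of the source cDNA yields one candidate siRNA
(N-containing windows are skipped), so a cDNA of length $G$ yields
$G - L + 1$ candidates. The activity filter is a named, versioned scheme so
results are reproducible and the rule set can be swapped without touching
the pipeline:

* `default-v1` — one point each for (a) GC fraction in [0.30, 0.60],
  (b) no homopolymer run ≥ 5, (c) A/T at sense position 19 (a thermodynamic
  asymmetry proxy); pass at ≥ 2 points. These are deliberately conservative,
  widely used sequence-level rules.
* `none` — everything passes. Because any activity filter can only remove
  true events, cot statistics are also computable unfiltered, and the dsRNA
  design guarantee (below) always uses `none`.

## Cot statistics, clean regions, and dsRNA pair design

Groups are formed per (source gene, off-target gene) with ≥ 2 distinct
member starts; orientation and mismatch count do not affect membership, and
duplicate loci collapse. Per-gene statistics are the group count, the
maximum group size, and coverage
$100 \cdot (\sum_g \text{size}_g) \cdot L / G$, which can exceed 100 % when
one siRNA belongs to several groups. Two overlapping source windows (starts
closer than *L*) count as distinct members — the enumeration is over all
possible siRNAs, and DICER phase is not predictable.

`clean_regions()` returns the maximal cDNA intervals that do not fully
contain two member sites of any one group (a member site is
$[s, s + L)$; a site truncated by a region boundary cannot arise from that
amplicon and counts as outside). Only consecutive members of a sorted group
constrain an interval, which gives a linear sweep over constraint pairs.
An optional UTR mask is subtracted afterwards — UTRs are less unique than
coding sequence and can be avoided on request.

`design_dsrna_pairs()` generalises from "pairs of sites" to the event that
actually ruins an experiment: region 1 and region 2 each containing ≥ 1
member of the same group, i.e. a shared off-target gene. Candidate regions
are laid on a 21-nt grid, each region takes the longest admissible length in
[min_len, max_len] (defaults 300/800), candidates are ranked by descending
combined length with ties broken by leftmost region 1 then region 2, and a
pair is emitted only if the off-target gene sets of the siRNA sites wholly
inside each region are disjoint. The grid makes the search deterministic and
coarse on purpose — dsRNA boundaries are not base-precise experimentally —
and every emitted pair is re-verifiable from scratch with the naive engine
(the tests do exactly that). When no pair exists the result is a structured
report listing the blocking off-target genes rather than an empty answer.

## The random-genome expectation

For an i.i.d. random genome, the expected number of gapless ≤ *k*-mismatch
matches of one *L*-mer is

$$E = S \cdot \frac{\sum_{i=0}^{k} \binom{L}{i} 3^i}{4^L},$$

with $S$ the number of window positions (doubled for both strands). At
*L* = 21, *k* = 3 the Hamming-ball numerator is 37,864. The formula ignores
edge effects and the dependence between overlapping windows; it is used to
size fixtures so that planted structure dominates background, and it is
checked in the tests term-by-term against exhaustive neighbour enumeration
at small *L* and by Monte-Carlo against the seeded engine on random
genomes.

## The synthetic-fixture generator

`generate_fixture()` emits FASTA + GFF3 + a ground-truth TSV for a genome of
single-transcript genes (one contig each, both strands, exon/intron/UTR
structure) with i.i.d. background sequence and planted repeats: copies of
chosen source-cDNA windows, mutated to an exact Hamming distance, placed in
a requested region class of a target gene, optionally reverse-complemented.
Identical specs produce byte-identical files.

What it emulates: the combinatorics the method operates on — shared
off-targets at controlled multiplicity, distance, region and orientation,
against a background whose match statistics follow the formula above. What
it does not: real genomes' repeat families, biased composition, splice-site
motifs, paralogy, or isoform complexity. Passing the suite therefore shows
algorithmic correctness (completeness, soundness, recovery, disjointness),
not that any particular organism has few or many cot-groups. Genome-scale
survey statistics from the original analysis depend on a specific historical
genome build and scoring table and are out of scope here; the qualitative
directions (intron filtering reduces counts; counts grow with gene length)
are reproduced on fixtures instead.

A planted window also drags its overlapping neighbours along: a window one
position away from a planted site often aligns to the target within the
mismatch budget too. Recovery assertions therefore check that planted starts
are among a group's members and that no *extra gene pairs* appear, not that
member lists equal the planted starts exactly.

## Numerical and interface choices

* Coordinates are 0-based half-open internally, 1-based in all written
  reports, matching GFF3 convention at the boundary.
* `word_size` must lie in [4, 15] so keys fit an R integer ($4^{15} < 2^{31}$).
* Candidate loci are deduplicated on (record, offset, orientation), keeping
  the verified mismatch count; hits are ordered by record, offset,
  orientation for deterministic output.
* Queries containing N are skipped with a warning rather than an error, so
  a scan over a cDNA with ambiguous stretches degrades gracefully.
* Reports embed the resolved configuration, a config hash and the package
  version; timestamps go to the stderr log only, so identical
  configurations give byte-identical files.
* Test problem sizes were chosen as the smallest at which the properties
  are meaningful: ~50 random target spaces of a few genes (≈ 5–10 kb) with
  200 queries each for engine equivalence at every k in 0..3, and a few
  hundred kilobases with a few hundred replicates for the Monte-Carlo
  check, where the Poisson standard error of the formula gives the
  acceptance band.

## Known limitations

* Gapless Hamming alignments only: no indels, no scoring matrices, and no
  seed-region (positions 2–8) miRNA-style weighting of mismatch positions.
* No RNA secondary structure, accessibility or expression weighting of
  off-target risk.
* The activity scheme is a documented stand-in, flagged as such; swap in a
  lab-specific rule set via `scoring_scheme()` if one is available.
* The design search is grid-based: it trades base-precise optimality for
  determinism and verifiability, and can in principle miss a feasible pair
  that exists only off-grid at unusual lengths.
* The in-memory index is rebuilt per run; persistence is out of scope at
  desk scale.
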