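# cotscan

Common off-target analysis and dsRNA design for RNAi reagents.

## The problem

In *Drosophila* and *C. elegans* RNAi, genes are silenced with long
(300–800 bp) dsRNAs that the cell dices into many ~21-nt siRNAs. Each siRNA
can also silence *off-target* genes it resembles (here: gapless alignment
with ≤ 3 mismatches over 21 nt). The classic control — a second,
non-overlapping dsRNA against the same gene — breaks down when siRNAs from
both dsRNAs share an off-target gene: the shared phenotype is then
misattributed to the intended target. `cotscan` measures how often this can
happen and designs dsRNA region pairs for which it cannot.

The central statistic is the **cot-group** (common off-target group): a set
of ≥ 2 siRNAs derived from one source gene that all map to the same
off-target gene. Per gene, `cotscan` reports the number of cot-groups, the
maximum group size, and the coverage
`100 × (Σ group sizes) × L / gene length` (L = 21; may exceed 100 %).

## The algorithm

Search is exact, via a seed table: every 9-nt word of the target space
(key space 4⁹ = 262,144) maps to its complete location list. A 21-nt query
splits into two 9-nt children plus a 3-nt remainder; for any hit with
i + j ≤ k mismatches in the children, looking up all Hamming variants of
child 1 (exact distance i) and child 2 (distance j) and joining locations
exactly 9 nt apart generates the candidate — so every possible alignment is
evaluated — and one direct verification at the locus settles the remainder
and the true mismatch count. Targets are indexed sense-strand only; queries
are searched in both orientations (a dsRNA yields both siRNA polarities).
Off-targets can be mapped against unspliced pre-mRNAs (default) or mature
transcripts, and intron-touching hits can be filtered.

A brute-force position-by-position Hamming scan (`naive_search()`) is a
first-class second engine; the test suite asserts that both engines return
identical hit sets everywhere.

## Worked example

Everything is testable offline: the fixtures module generates a synthetic
genome with *planted* shared off-targets and a ground-truth table.

```r
library(cotscan)

spec <- fixture_spec(seed = 7, n_genes = 6,
  planted_repeats = list(
    plant_spec(1, c(100, 650), 4, "exon", mismatches_each = 1)))
fix    <- generate_fixture(spec, tempfile("demo"))
models <- load_gene_models(fix$fasta, fix$gff)
genome <- load_genome(fix$fasta)

ts  <- target_space(models, genome, mode = "premrna")
idx <- build_seed_index(ts)
idx
#> <seed_index> word_size=9 (key space 262,144), 6 record(s), 7906 location(s), 7796/262,144 keys occupied

gs    <- extract_sequences(models[["FG001"]], genome)
cands <- score_sirnas(enumerate_sirnas(gs), "default-v1")
hits  <- map_offtargets(cands, idx, ts, k = 3)
groups <- form_cot_groups(hits)
groups[, c("source_gene", "offtarget_gene", "size")]
#>   source_gene offtarget_gene size
#> 1       FG001          FG004   10
cot_stats(groups, gene_length = gs$gene_length)
#>   n_cot_groups max_group_size coverage_percent gene_length
#> 1            1             10         23.41137         897
```

The two windows planted at cDNA starts 100 and 650 of gene FG001 (one
mismatch each, into an exon of FG004) come back as one cot-group; the
overlapping neighbours of each planted window also align within the
3-mismatch budget, hence 10 members. Designing dsRNA pairs then avoids
splitting any group across the two regions:

```r
d <- design_dsrna_pairs(gs, hits, min_len = 250, max_len = 600)
d
#> <dsrna_design> FG001: 5 clean pair(s)
head(d$pairs, 2)
#>   region1_start region1_end region2_start region2_end combined_length
#> 1           105         357           357         897             792
#> 2           105         378           378         897             792
```

Both regions of every emitted pair have disjoint off-target gene sets
(region 1 excludes the sites around start 100; region 2 holds only the 650
cluster), so no single off-target gene can be silenced by both dsRNAs.

A thin command-line wrapper is included at `inst/cli/cotscan.R`
(`index` / `scan` / `design` / `fixtures` subcommands over a YAML config).

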