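# archvir

Viruses infecting marine Archaea are critical players in oceanic microbial
ecosystems but are almost invisible in reference databases: most genes on a
mesophilic archaeal virus contig have no confident annotation at all, and
the few that do are easily shadowed by phage hits. `archvir` identifies
putative archaeal virus contigs in viral metagenomes by a *majority-rules
consensus* over per-gene taxonomic annotations, and provides the
surrounding computations a virome survey needs: keyword-lexicon affiliation
of gene lineages, greedy ANI dereplication of contigs into viral
populations, coverage-normalized abundance matrices with alpha/beta
diversity statistics, and a seeded synthetic benchmark generator for
measuring classifier performance.

It is aimed at viral ecologists working with assembled viromes (e.g. from
oxygen minimum zones or other water-column habitats) who have gene-level
annotation tables or BLASTp tabular hits and want a transparent, tunable,
reproducible screen for archaeal virus candidates.

## The classification rules

For each contig, let `n` be its number of annotated genes (best-hit taxon
group ≠ unclassified), `f` the fraction of annotated, non-eukaryotic-virus
genes affiliated with reference archaeal viruses, and `b_a`, `b_p` the best
(maximum) BLASTp bit-scores among its archaeal-virus and phage gene
annotations. With defaults (fractions 2/3 and 1/3, bit-score floor 75):

| Category | Rule |
|---|---|
| 1 (main) | `n ≥ 3`, `f > 2/3`, `b_a > 75`, `b_a > b_p` |
| 1 (few-annotation clause) | `n ∈ {1, 2}`, all annotated genes archaeal virus, `b_a > 75` |
| 2 | `n ≥ 3`, `f > 2/3`, `b_a > 75`, `b_p ≥ b_a` (phage hit outscores) |
| 3 | `n ≥ 3`, `1/3 ≤ f ≤ 2/3`, `b_a > 75`, `b_a > b_p` |
| none | anything else |

Rules are evaluated in precedence order 1 → 2 → 3; eukaryotic virus hits
are counted but excluded from `f`. Every threshold is a
`category_thresholds()` option.

Downstream, candidate contigs > 10 kb are collapsed into viral populations
at ≥ 95% average nucleotide identity across ≥ 80% of the shorter sequence
(greedy longest-first clustering), abundances are computed as
`(summed depth / contig length) / sample read bases × 10^9` (optionally
`log10(1 + x)`), and community structure is summarized with richness,
Shannon–Wiener `H' = −Σ p_i ln p_i`, Pielou's `J = H'/ln S`, Bray–Curtis
dissimilarity and a permutation Mantel test.

## Worked example

```r
library(archvir)

ann <- read_annotation_tsv(
  system.file("extdata", "example_annotations.tsv", package = "archvir")
)
cl <- classify_contigs(ann)
cl
#> Contig consensus classification
#>   3 contigs: 2 category 1, 0 category 2, 0 category 3, 1 rejected

tidy(cl)[, c("contig_id", "category", "n_genes_total", "n_annotated",
             "arch_fraction", "max_bit_archaeal", "max_bit_phage")]
#>       contig_id category n_genes_total n_annotated arch_fraction
#> 1  omz_phage_01     none             7           4             0
#> 2 omz_sparse_01        1            52           2             1
#> 3  omz_virus_01        1             8           5             1
#>   max_bit_archaeal max_bit_phage
#> 1               NA         250.1
#> 2            100.3            NA
#> 3            210.5            NA
```

`omz_virus_01` (5 of 8 genes archaeal virus, top bit-score 210.5) passes
the main category-1 rule. `omz_sparse_01` shows why the few-annotation
clause exists: only 2 of its 52 genes could be annotated, but both hit
archaeal viruses above the bit-score floor, so it is reported as a
category-1 candidate rather than discarded. The phage contig, with zero
archaeal-virus affiliations, is rejected. The `rule_trace` column of
`tidy(cl)` records each threshold decision; `autoplot(cl)` plots contigs
against the decision boundaries.

A CLI wrapper over the same functions ships in
`system.file("exec", "archvir.R", package = "archvir")` with subcommands
`classify`, `derep`, `ecology`, `simulate` and `benchmark`; every run
writes a `provenance.json` (inputs, thresholds, seed, version).

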