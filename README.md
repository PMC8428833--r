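# panpav

Map-to-pan gene presence/absence variation (PAV) analysis for plant
pan-genomes.

Pan-genome studies of crops like soybean assemble sequence from many
accessions, merge what is missing from the reference into a *pan-genome*,
and then ask, for every annotated gene and every accession: is this gene
there? `panpav` implements the analysis layer of that question for
researchers doing map-to-pan work — people who already have per-accession
read alignments (as depth tables), a pan-genome annotation (GFF3), contig
alignment summaries, and long-read structural-variant calls, and who need
the downstream statistics done correctly and reproducibly.

## What it computes

**Presence calling.** A gene is present in an accession when breadth of
coverage reaches both thresholds of the map-to-pan rule:

    gene-body coverage >= 0.75  AND  CDS coverage >= 0.95

(both inclusive; breadth = fraction of positions covered at depth >=
`depth_min`, default 1). Calls over all genes and accessions form the binary
PAV matrix `M[g, a] ∈ {0, 1}`.

**Frequency classification.** With presence frequency *f* = count/n, genes
are *hardcore* (f > 0.99), *softcore* (0.95 < f ≤ 0.99), *shell*
(0.05 ≤ f ≤ 0.95) or *cloud* (f < 0.05); *core* = hardcore ∪ softcore
(loss rate < 0.05), *variable* = shell ∪ cloud.

**Rarefaction.** Pan (union) and core (intersection) gene counts over random
accession subsets of size 1..N (100 iterations, prefix design), with
saturation fits P(n) = A·n^γ + C, Δ(n) = k·n^(−α), K(n) = B·e^(−n/τ) + Ω
and the classic openness criterion (pan closed iff α > 1).

**Population structure.** Simple-matching or Jaccard PAV distances, genotype
PCA (centered, unscaled), neighbor-joining trees, Mantel comparison against
SNP distances, and a per-clade gene-loss Welch t-test.

**Nonreference extraction.** Contig classification against reference
alignment summaries (≥500 bp contigs; unaligned fragments >450 bp), fragment
excision, CD-HIT-style greedy redundancy clustering, contaminant filtering
from taxon-labelled hit tables, and novel-sequence accumulation curves.

**Long-read validation.** Deletion–gene overlap support rates and k-mer
containment recovery of novel sequence within insertion calls.

**Evolutionary rates.** Nei–Gojobori (NG86) dN/dS with Jukes–Cantor
correction and a core-vs-variable contrast.

**Synthetic data.** A fully seeded generator
(`sim_config()`/`simulate_pangenome()`/`simulate_coverage()`/
`simulate_sv_calls()`/`simulate_snp_distance()`) produces ground-truthed
pan-genomes at study scale (defaults: 204 accessions × 54,531 genes, observed
category proportions, two clades), so every stage is testable end to end
without sequencing data.

## Worked example

Simulate a pan-genome, call PAVs from the coverage evidence, classify, and
run the structure analyses:

```r
library(panpav)

cfg <- sim_config(n_accessions = 100, n_genes = 6000, seed = 42)
sim <- simulate_pangenome(cfg)
cov <- simulate_coverage(sim, seed = 43)

pav <- build_pav_matrix(sim$genes, cov)
pav
#> <pav_matrix> 6000 genes x 100 accessions (96.1% present)

classification_summary(categorize_genes(pav))
#> # A tibble: 4 × 3
#>   category     n    pct
#>   <fct>    <int>  <dbl>
#> 1 hardcore  5456 90.9
#> 2 softcore   122  2.03
#> 3 shell      397  6.62
#> 4 cloud       25  0.417

rc <- pan_core_curves(pav, n_iterations = 100, seed = 44)
fit_saturation(rc)
#> <saturation_fit>
#>   pan-genome: closed (new-gene decay alpha = 1.816)
#>   core-genome: closed

d <- pav_distance(pav)
snp <- simulate_snp_distance(sim, mixing = calibrate_snp_mixing(sim), seed = 45)
mantel_test(d, snp, n_perm = 999, seed = 46)
#> Mantel test: r = 0.4956, p = 0.001 (greater, 999 permutations, n = 100)

clade_gene_loss(pav)$test
#> # A tibble: 1 × 5
#>   estimate_a estimate_b     t    df  p_value
#>        <dbl>      <dbl> <dbl> <dbl>    <dbl>
#> 1       250.       213.  18.2  96.6 4.95e-33
```

Reading the numbers: 90.9% of genes are hardcore and 93% core — the
simulated pan-genome, like the soybean study conditions it mirrors, is
dominated by genes shared by nearly everyone, and the saturation fit calls
the pan-genome closed (new-gene discovery decays faster than 1/n). The
Mantel correlation of ≈0.5 says PAV distances and SNP distances rank
accession pairs similarly. The clade contrast shows clade I accessions
losing on average ~37 more genes than clade II (p ≈ 5e-33).

Plot helpers: `autoplot(rc)` (rarefaction ribbons), `autoplot(pav_pca(pav))`,
`plot_category_summary()`, `plot_accumulation()`. Fitted and test objects
have broom-style `tidy()`/`glance()` methods.

A thin command-line interface over the same functions ships in
`inst/cli/panpav.R` (subcommands `simulate`, `call-pav`, `classify`,
`rarefy`, `structure`, `extract-nonref`, `validate-longread`, `dnds`; run it
without arguments for usage).

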