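---
title: "Map-to-pan PAV analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-to-pan PAV analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpav)
```

`panpav` implements genic presence/absence-variation (PAV) analysis for plant
pan-genomes built with a *map-to-pan* strategy: short reads from every
accession are aligned to one pan-genome (reference plus assembled
nonreference sequence), and a gene is declared present in an accession when
enough of it is covered by reads. Everything downstream — frequency
classification, rarefaction, population structure, long-read validation —
consumes the resulting binary genes × accessions matrix. This vignette
explains the models and the choices behind them; the README shows the
worked example.

## The presence rule

The unit of evidence is breadth of coverage: the fraction of a region's
positions covered at read depth ≥ `depth_min` (default 1; the depth cutoff
behind "covered" is a free choice in map-to-pan work, so it is exposed as a
parameter of `read_depth_table()` rather than hard-wired). A gene is called
**present** when

* gene-body breadth ≥ 0.75, and
* CDS breadth ≥ 0.95,

both thresholds inclusive (`presence_rule()`). The CDS criterion is the
stringent one — coding sequence must be almost fully covered — while the
gene-body criterion tolerates uncovered introns/UTRs. Two properties follow
directly from the definition and are enforced by tests: adding covered
positions can never flip a call from present to absent, and calls are
invariant to how the covered positions are split into intervals.

All internal coordinates are 0-based half-open; GFF3 and depth tables are
converted at the boundary (1-based inclusive). Interval arithmetic is
delegated to IRanges.

## Frequency categories

With presence frequency *f* = presence count / accessions, genes fall into

| category | band | superclass |
|---|---|---|
| hardcore | (0.99, 1] | core |
| softcore | (0.95, 0.99] | core |
| shell | [0.05, 0.95] | variable |
| cloud | [0, 0.05) | variable |

The boundary semantics deserve a note: descriptions of these bands in the
literature are often rounded ("95–99%", "5–95%") and sometimes contradictory
between a figure caption ("core = ≥95%") and a methods definition ("core =
loss rate < 0.05", i.e. strictly more than 95% presence). The partition
above is the only one simultaneously consistent with a strict ">99%"
hardcore bound, a strict "<5%" cloud bound, and "loss rate ≥ 0.05 ⇒
variable" (so a gene present in exactly 95% of accessions is shell).
`categorize_genes()` compares integer presence counts against `threshold ×
n` with a 1e-9 guard instead of comparing floating-point frequencies, so
band edges are exact at any accession count.

## The synthetic-data generator

Real map-to-pan inputs are hundreds of whole-genome sequencing runs; the
generator (`sim_config()`, `simulate_pangenome()`, `simulate_coverage()`,
`simulate_sv_calls()`, `simulate_snp_distance()`) stands in for them with a
ground-truthed model whose defaults are the conditions of a
cultivated-soybean-scale study: 204 accessions, 54,531 genes, and category
fractions fixed at the observed 49,431/1,401/3,402/297 proportions.

Design of the truth model:

* Category assignment is deterministic by count (largest remainder), so
  realized proportions match the configuration exactly — parameter-recovery
  tests stay sharp.
* Truth frequencies: hardcore exactly 1.0 (the ">99%" class in real data is
  a calling artifact, not a generative one); softcore uniform on
  (0.955, 0.99); shell uniform on (0.06, 0.94); cloud uniform on
  (1/n, 0.045). The 0.005–0.01 guard margins reduce — but at the hardcore
  boundary cannot eliminate — band-crossing by binomial sampling noise at
  n = 204: a softcore gene at truth frequency 0.985 still has a ≈25% chance
  of being sampled into the hardcore band. Classification of a *sampled*
  matrix therefore shows a ≈0.5-point excess of hardcore over the generative
  fractions; this is inherent to sampling, not a defect of the classifier
  (which is exact on the matrix it is given).
* Two clades: half the accessions form clade II, and half the shell genes
  are clade-informative with presence frequencies split ±`clade_bias`/2
  between clades (clade I carries the extra absence). Defaults
  `clade_bias = 0.22`, `clade_informative_frac = 0.5` were chosen so the
  simulated clades reproduce two observed features of real PAV structure:
  the split is recoverable from the NJ tree (a "highly supported" two-clade
  structure), and mean per-accession gene loss differs between clades by
  roughly 19%. Weaker settings produce clades that no distance-based method
  can recover, which would contradict the structure being emulated.
* Coverage: present genes draw body breadth ≥ 0.9 and CDS breadth ≥ 0.97,
  absent genes ≤ 0.4 and ≤ 0.5 — margins chosen so noise-free calls
  reproduce truth exactly under the (0.75, 0.95) rule. `coverage_noise` is a
  mislabel-injection probability: with probability ε a pair is drawn from
  the opposite regime, making ε the *expected call error rate*, an analytic
  handle used by the error-rate tests.
* The SNP distance matrix is `mixing · D_PAV + (1 − mixing) · noise` with
  the noise rescaled to the spread of the PAV distances;
  `calibrate_snp_mixing()` bisects `mixing` against the Mantel correlation
  (one fixed noise realization makes the response deterministic and
  monotone), emulating a Mantel statistic of ≈0.49 between marker systems.

What the generator deliberately does **not** emulate: read-level noise
(mapping quality, GC bias), linkage between neighboring genes, copy-number
variation, population admixture beyond two clean clades, or any sequence
evolution behind the SNP distances. Passing tests therefore demonstrate
correctness of the *computations* under a controlled model, not robustness
to every artifact of real sequencing data.

All generator randomness flows from a single seed (`sim_config(seed = )`),
restored on exit so callers' RNG streams are untouched; the same seed gives
byte-identical output.

## Rarefaction and saturation

`pan_core_curves()` estimates pan size (genes present in ≥1 sampled
accession) and core size (present in all sampled) over subsample sizes
1..N. Each of the `n_iterations` (default 100) iterations draws one random
accession order and evaluates all prefixes, which makes pan non-decreasing
and core non-increasing within an iteration by construction, and makes the
per-size mean an unbiased estimate of the uniform-subset expectation (a
prefix of a uniform permutation is a uniform subset). Internally the curves
are computed from each gene's first-presence and first-absence rank in the
permuted order, so an iteration costs two `max.col()` passes rather than N
matrix scans — study-scale matrices (54,531 × 204, 100 iterations) run in
seconds. `exhaustive = TRUE` enumerates all orders (≤7 accessions) for exact
means, used by the enumeration tests.

`fit_saturation()` fits the standard saturation family on the mean curves:
`P(n) = A·n^γ + C` (pan), `Δ(n) = k·n^(−α)` (new genes per added accession,
fit log-log on successive differences; zero differences — a fully saturated
tail — are excluded, and a curve with no positive increments reports
α = ∞), and `K(n) = B·exp(−n/τ) + Ω` (core). Verdicts: the pan-genome is
*closed* when new-gene discovery decays faster than 1/n (α > 1); the core
genome is *open* when the fitted core curve still drops by more than 0.5
genes between N−1 and N. Nonlinear fits use `minpack.lm::nlsLM`;
non-convergence yields NA parameters plus the solver message and no verdict.

## Population structure

PAV distances are *simple matching* (fraction of genes whose presence state
differs; the default, appropriate when absence is as informative as
presence) or *Jaccard* (ignores shared absences). PCA centers but does not
scale the binary columns — the genotype-PCA convention — with a
deterministic sign convention (largest-magnitude loading positive). Trees
are neighbor-joining (`ape::nj`) on the PAV distances, with taxa presented
in label order for deterministic ties and negative branch lengths clamped to
zero, the excess moved to the sister branch. NJ replaces likelihood tree
building deliberately: the tree's role here is clade assignment, NJ is fully
specifiable and exactly testable (it reconstructs additive metrics
perfectly), and the recoverable contract is the two-clade split, not the
fine topology.

`tree_bipartition()` assigns the two clades. Each internal edge induces a
bipartition; the chosen one maximizes mean between-clade minus mean
within-clade distance with at least two tips per side. (The tempting
"longest internal edge" shortcut fails in practice: on study-scale NJ trees
a pair of outlier accessions can sit on the longest edge, yielding a 202/2
"split".) The per-clade gene-loss contrast (`clade_gene_loss()`) is a Welch
two-sample t-test on per-accession absence counts.

The Mantel test is implemented directly (Pearson correlation of
upper-triangle entries; simultaneous row/column permutation of the second
matrix; `p = (1 + #{r* ≥ r}) / (1 + n_perm)`, one-sided "greater" by default
since the claimed association is positive) so that seeding and the exact
small-n enumeration mode (`exact = TRUE`, ≤7 labels) are under the package's
control; tests cross-check the statistic against `vegan::mantel`.

## Nonreference-sequence extraction

`classify_contigs()` applies the standard novel-sequence rules: contigs
under 500 bp are dropped; contigs with no reference alignment are fully
unaligned; contigs with an alignment and an unaligned fragment *strictly*
longer than 450 bp are partially unaligned and their qualifying fragments
are excised. Redundancy removal is greedy longest-first clustering at 90%
identity — the CD-HIT convention of `-c 0.9`, with identity measured as
matches in the best local alignment divided by the *shorter sequence
length*. A raw matches/alignment-length ratio is not usable here: under
local alignment two unrelated sequences always share some short perfect
word, so that ratio is ≈1 for everything. The literature quotes both 90%
and 95% for this step; the threshold is a parameter
(`extraction_config(redundancy_identity = )`). Pairs differing more than
two-fold in length are compared by k-mer containment of the shorter in the
longer instead of alignment. Contamination filtering consumes precomputed
taxon-labelled hit tables: a contig is removed when its minimum-e-value hit
(ties broken by class priority organellar > microbial > non-Viridiplantae,
then lower identity) is not nuclear plant sequence; contigs without hits are
retained.

`accumulation_curve()` gives cumulative novel bp over incremental random
accession subsets (default step 20, 100 random orders), by the same
first-occurrence trick as rarefaction; its final value is the total union
length for every order.

## Long-read validation

Short-read absence calls are validated against long-read structural
variants in two directions. *Deletions*: an absent gene is supported when a
deletion on the same sequence overlaps its gene body by at least 1 bp
(partial or complete overlap; no reciprocal-overlap requirement — both are
parameters). Both the pooled support rate and the mean of per-accession
rates are reported, the two natural aggregations. *Insertions*: a novel
sequence is recovered when at least `min_containment` of its canonical
31-mers occur among the insertion sequences' canonical k-mers — an
aligner-free stand-in for remapping unaligned reads onto the insertion
catalogue. Note the interaction of divergence and k: at 1% divergence the
expected 31-mer survival is 0.99³¹ ≈ 0.73, so the default containment
threshold of 0.8 only suits near-identical sequence; for 1%-divergent
insertion catalogues a threshold of 0.5 separates true containment (≈0.73)
from random background (≈0) with wide margins, and that is what the
round-trip analyses use.

## NG86 dN/dS

`ng86_dnds()` is the classic Nei–Gojobori method: per-codon synonymous site
counts from the nine single-nucleotide mutations (averaged over the two
sequences; S + N equals the nucleotide length exactly), observed differences
averaged over all minimal mutational pathways between differing codons, and
Jukes–Cantor correction `d = −(3/4)·ln(1 − (4/3)p)`. Conventions, stated
because NG86 implementations differ: mutations creating a stop codon count
as nonsynonymous in the site counts; pathways passing through a stop codon
are excluded from the average unless every pathway does; codon pairs with
ambiguity characters are skipped; an internal stop is an error; `p ≥ 3/4`
makes the correction undefined (reported as NA with a warning, easily
reached on very short alignments); the ratio is NA when dS = 0. The
upstream questions — which orthologs, which aligner, which filtering — are
outside the package: `dnds_table()` expects ready codon alignments, and any
core-vs-variable contrast is only as good as those inputs.

## Numerical and scale choices

Test and example problem sizes are chosen so the full suite exercises every
path at desk scale: exhaustive oracles run at ≤5 accessions, ≤3 codons, or
24 permutations; end-to-end coverage-to-classification recovery runs at 200
accessions × 2,000 genes; classification, rarefaction, distances, trees and
the Mantel test also run at the full 204 × 54,531 scale in the acceptance
script (the efficient rarefaction makes this cheap). Boundary behavior is
pinned by construction: coverage fixtures realize exact covered fractions,
so threshold tests hit 0.75/0.95 precisely rather than approximately.

## Known limitations

* The PAV matrix is binary; copy number is out of scope.
* Clade assignment assumes exactly two clades; more structure needs
  user-supplied labels.
* The redundancy clustering is exact-alignment based and intended for
  desk-scale fragment sets (hundreds to thousands of 0.5–5 kb sequences),
  not for replacing CD-HIT on millions of sequences.
* `simulate_coverage()` materializes one row per gene × accession interval;
  at the full 54,531 × 204 scale this is memory-hungry, which is why the
  coverage-calling stage of the acceptance analyses runs at 2,000 genes
  while matrix-level stages run at full scale.
* dN/dS site counting uses the standard genetic code only.
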