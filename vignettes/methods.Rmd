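---
title: "Methods: comparative genomics of phytophagous insect genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of phytophagous insect genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytophagr)
library(dplyr)
```

`phytophagr` reimplements, as tested and reusable functions, four
comparative-genomics computations that insect genome projects typically run
as one-off custom scripts: (1) classification of every gene of every species
into conservation-breadth categories over a three-set species design,
(2) a DNA-similarity screen for bacterial-to-eukaryote horizontal gene
transfer (HGT), (3) a cross-species domain-count analysis of gene-family
expansions, and (4) an exact-test differential-expression (DE) flagging
procedure. A fifth module simulates every input with known ground truth, so
the whole pipeline is testable at desk scale with no downloads. This
vignette records the models, the tunable parameters and their defaults, the
numerical choices, and the limits of what the synthetic fixtures can show.

## Conventions

All genomic intervals are 0-based half-open internally; conversion from the
1-based inclusive conventions of GFF3 and tabular alignment files happens
once, in the readers, so no downstream arithmetic mixes conventions. Hit
records keep their file-format 1-based query coordinates (they are format
fields, not intervals) and are converted where regions are built. Strand is
recorded but ignored by the HGT screen, which is DNA-similarity based.

Every significance gate in the package is strict. An E-value exactly at the
`1e-5` threshold is not significant; a log fold change of exactly 1.0 or an
adjusted p of exactly 0.05 is not flagged; a domain family whose maximum
count is exactly 5 is not reported. These boundaries follow the printed
conventions of the procedures being reimplemented and are asserted in the
test suite.

## Three-set orthology classification

The species under study are partitioned into three disjoint sets — by
default five Coleoptera, five Lepidoptera/Diptera, and five outgroup
insects, named by 5-letter genome codes. An orthologous group (OG) *counts*
in a set when it contains genes from at least `min_species_per_set`
(default 2) distinct species of that set; its *span* is the number of
counting sets (`three_set`, `two_set`, `one_set`, or `unshared`).

Genes inherit categories from their OG's span. Genes in three-set OGs are
`universal_single` or `universal_multi` according to whether their species
has exactly one gene in the OG. Genes in two- and one-set OGs are `two_set`
and `set_restricted_ortholog`. Genes with no OG at all — and genes in
`unshared` OGs, which fail the sharing threshold everywhere — fall through
to homology fallbacks: a significant hit (E < 1e-5) to any other arthropod
gene makes the gene an `arthropod_homolog`; failing that, a significant hit
to a *different* gene of its own genome makes it a `self_homolog` (a gene's
trivial hit to itself never counts, otherwise every gene would be
self-homologous); otherwise the gene is `unique`. A gene with both kinds of
evidence is `arthropod_homolog`, matching the conventional ordering of the
fallback classes. The seven categories are mutually exclusive and
exhaustive; `summarize_partition()` additionally reports two derived
super-class views — `widespread` (all universal_single + universal_multi
genes over three-set OGs) and `universal_core` (genes in OGs containing
every species of the universe) — because both views are standard in
comparative summaries.

Treating sub-threshold (`unshared`) OGs as orthologs would invent a
category the classification lacks, so those genes use the fallbacks; this
is a design decision, asserted by the closed-loop simulator test.

`copy_number_split()` tallies, per species over all three-set OGs, genes in
OGs where the species has one copy versus more than one; counts are gene
counts, not OG counts.

The implementation is dplyr joins over membership triples; its oracle in
the test suite is an intentionally naive nested-loop recount, and the two
agree exactly on hundreds of random tables.

## The HGT screen

The screen takes tabular DNA-similarity hits of genomic scaffolds against a
bacterial database and proceeds in five steps:

1. **Gate and merge** (`find_bacterial_regions()`): hits with E >= 1e-5 are
   dropped; significant hits on one scaffold with overlapping query
   intervals merge into a region (a `gap` parameter, default 0, can bridge
   near-adjacent hits). The region carries its best hit — minimum E-value,
   ties by bit score, then subject id.
2. **Conserved-gene exclusion** (`screen_region()`): the best E-value among
   animal-database hits overlapping the region is compared with the
   bacterial E-value; the region is excluded as a slowly evolving conserved
   gene iff the animal E-value is *strictly* smaller. Ties and missing
   animal hits retain the candidate. Any overlap with the region interval
   triggers the comparison; no proximity threshold beyond overlap is
   imposed.
3. **Age classification** (`classify_age()`): identity >= 90% is `recent`;
   identity <= 80% with at least one indel event is `degrading`; everything
   else is `intermediate`. The thresholds generalize the two canonical
   regimes (about 95% identity for recent insertions; 70–71% with indels
   for old, degrading ones) into an explicit policy object with an
   intermediate class, and live in configuration, not code.
4. **Junction confirmation** (`confirm_junctions()`): a genuine integration
   leaves read pairs spanning both insertion junctions reproducibly across
   sequencing libraries. A candidate is confirmed when at least
   `min_libraries` (default 2, the weakest faithful reading of "multiple")
   distinct libraries have evidence within `window` (default 50) bases of
   *each* boundary.
5. **Flanking genes** (`flanking_genes()`): the nearest non-overlapping
   gene on each side gives the eukaryotic context of the insertion.

Candidate expression is deliberately not part of the verdict; an optional
per-candidate flag is carried for reporting only.

## The built-in aligner and its statistics

For fully self-contained runs the package ships a Smith–Waterman local
aligner with affine gaps (Gotoh's algorithm, compiled code). A gap run of
length $L$ scores $g_o + (L-1)\,g_e$; identity is matches over aligned
columns with gap columns counting as non-matches, reported to one decimal
as tabular search output does. E-values use the Karlin–Altschul form

$$E = K \, m \, n \, e^{-\lambda S}$$

with documented toy defaults $K = 0.1$, $\lambda = 0.5$. These are not
database-calibrated statistics: externally produced tabular hits are the
production path, and the built-in aligner exists for desk-scale fixtures
where every value can be checked against a brute-force DP oracle.

One numerical point matters in practice: $e^{-\lambda S}$ underflows to
zero in double precision once $\lambda S$ exceeds about 745. Kilobase-scale
high-identity alignments reach scores of ~2000, so `align_windows()` — the
helper that runs the aligner over scaffold windows against a database —
defaults to $\lambda = 0.25$, keeping E-values representable; otherwise the
screen's strict E-value comparisons would degenerate into ties at zero.
The alignment itself is unaffected ($\lambda$ only scales the reported
statistics, monotonically in the score).

## Domain-count expansion analysis

`build_count_matrix()` counts genes per (domain accession, species) cell at
gene level: a gene with a domain contributes exactly one count regardless
of repeated matches along the protein, because family-size comparisons are
about gene counts, not match counts. `flag_expansions()` reports a domain
iff its maximum per-species count strictly exceeds 5 (configurable), the
standard "potential expansion" operationalization; all tied arg-max species
are listed. `orthology_status_partition()` splits each species' domain
genes into single-copy orthologs, co-ortholog (multi-copy) genes, and
domain matches with no OG at all; the three bins always sum to the count
matrix cell. `enrichment_vs_mean()` is the focal-species headline ratio
(focal count over non-focal mean), with accession groups summed first when
a subfamily group is supplied; a zero non-focal mean yields `Inf` and is
flagged degenerate, and 0/0 is `NaN` (undefined). Subfamily grouping
schemes themselves are caller-supplied configuration.

## Exact-test differential expression

The DE procedure mirrors a small two-condition feeding-assay design (four
replicates per condition by default). Genes with fewer than ten reads in
total are removed. Counts are quantile-normalized: every sample is mapped
onto the reference distribution formed by row means of the sorted columns;
ties receive the mean of the reference values they span
(`limma::normalizeQuantiles(ties = TRUE)` provides exactly this step).
Each gene is then tested with a two-sided exact test on the 2×2 table
`[gene_trt, rest_trt; gene_ctl, rest_ctl]`, where `rest` is the condition
library total minus the gene count: conditioning on the margins, the
treatment count is hypergeometric and the two-sided p is the total
probability of all tables no more probable than the observed one (the
standard two-sided convention, with a `1 + 1e-7` relative tolerance
absorbing floating-point noise in the equal-probability tail). P-values are
Benjamini–Hochberg adjusted, and genes are flagged iff `|logFC| > 1` and
`adj_p < 0.05`, both strict, in either direction of change.

Two interpretation points are worth stating plainly:

* **Normalized logFC, raw-count test.** The reported log fold change is
  computed from quantile-normalized within-condition totals (with a
  pseudocount of 0.5 stabilizing zeros), while the exact test runs on raw
  count sums against raw library-size margins, where its hypergeometric
  model is meaningful. `gene_exact_test()` itself, called directly,
  computes logFC from the numbers it is given.
* **Replicate dispersion is unmodeled.** Summing replicates within
  condition before an exact test treats counts as Poisson-like; with
  overdispersed data the p-values are anti-conservative. The flagging
  still controls its empirical null rate at the default thresholds because
  the `|logFC| > 1` condition dominates: under the null the log ratio of
  condition sums concentrates well inside ±1. Users needing calibrated
  per-gene inference under dispersion should treat the p-values as ranks.
  Relatedly, quantile normalization assumes similar count distributions
  across samples; with strongly asymmetric, one-directional differential
  expression it (like any global normalization without a composition
  correction) biases null genes' fold changes, which is why the power
  fixture below plants balanced up- and down-regulation.

## The simulators

`simulate_gene_families()` runs duplication/loss on a species tree (default:
a stylized 15-tip tree over the three default sets). Each family starts as
one root copy; along a branch of length $t$ each incoming copy is lost with
probability $1 - e^{-\mu t}$, and each survivor duplicates once with
probability $1 - e^{-\lambda t}$. One event round per branch keeps the
simulator simple and exactly seedable; within-branch re-duplication of new
copies is deliberately not modeled. Truth categories are computed directly
from the realized presence pattern — never by the classifier under test —
and the simulator also emits *perfect* homology fallback files (hits
between surviving members of sub-threshold families), which is what an
oracle homology search would return. Default rates 0.1/0.1 per unit branch
length give predominantly universal families with a realistic minority of
restricted ones; tests that need many lineage-restricted families raise the
loss rate explicitly.

`simulate_hgt_genome()` plants diverged copies of random bacterial source
segments into a uniform-random host (rejection-sampled placement with a
minimum separation; an error after 1000 failed draws signals an infeasible
configuration). Substitutions occur per site with probability `divergence`;
indels per site at `indel_rate` (single-base by default, geometric lengths
optionally). Realized identity is recomputed from the construction
alignment — matches over columns, gap columns counting against — not
assumed from the nominal divergence. Junction evidence is emitted for every
insertion at both boundaries in all libraries. Decoy "conserved genes" are
host segments whose exact copy goes into the animal database and a more
diverged copy (12% divergence by default) into the bacterial database, so
the animal hit always wins and the screen must exclude them. A window
table (flank 500 bp) covering every planted locus and decoy lets the
desk-scale aligner run all windows against the whole database instead of
scanning a megabase genome.

`simulate_domain_annotations()` draws background counts uniformly on
`0..background_max` and sets planted cells exactly; planted counts must
exceed the background maximum. `simulate_counts()` draws negative-binomial
counts with means $\mu\,2^{\pm \mathrm{lfc}/2}$ per condition and variance
$\mu + \phi \mu^2$; $\phi = 0$ degenerates to Poisson (checked by a moment
test). All simulators are pure functions of their seed.

### What the fixtures do and do not show

The synthetic data exercise the *logic* of each analysis — set
intersection, E-value gates, merging, tie rules, boundary strictness, FDR
arithmetic — under known truth. They do not emulate real genome
composition (repeats, GC structure), real orthology-resource clustering
noise, isoform redundancy in domain annotation, or read-level error; a
passing suite therefore certifies the computations, not the upstream
resources those computations are usually fed from. Headline numbers from
any real genome project additionally depend on its assembly, annotation
and database versions, and are out of scope here.

## Problem sizes

The shipped checks run, per invocation: 200 random OG tables (≤ 8 species,
≤ 50 OGs) against the naive recount oracle; 1000-family closed-loop
simulations; a 1 Mb host with 50 planted 2 kb insertions at 5% divergence
plus 10 decoys (the aligner's windowed all-vs-all pass is the dominant
cost, a few minutes of CPU) and a smaller 30%-divergence indel fixture;
the exhaustive exact-test sweep over all 2×2 tables with margins ≤ 30; and
2000-gene null and power count simulations. These sizes were chosen as the
smallest at which each property is sharply testable.

## A worked mini-example

```{r example}
sim <- simulate_gene_families(200, dup_rate = 0.3, loss_rate = 0.8, seed = 1)
cls <- classify_genes(sim$table, default_species_partition(),
                      arthropod_hits = sim$arthropod_hits,
                      self_hits = sim$self_hits, genes = sim$genes)
summ <- summarize_partition(cls, sim$table, default_species_partition())
glance(summ)
head(copy_number_split(sim$table, default_species_partition()), 3)
```

```{r example-de}
lfc <- c(rep(3, 20), rep(-3, 20), rep(0, 360))
simc <- simulate_counts(n_genes = 400, baseline_mean = 150,
                        dispersion = 0.2, true_logfc = lfc, seed = 2)
res <- run_de(simc$counts, simc$conditions)
glance(res)
```

## Known limitations

* The exact test's p-values ignore replicate-level dispersion (see above);
  moderated NB pipelines are intentionally out of scope.
* The aligner is a full dynamic-programming implementation without
  seed-and-extend heuristics; it is meant for windows and fixtures, not
  genome-scale search.
* Karlin–Altschul parameters are nominal, so absolute E-values from the
  built-in aligner are comparable within a run but not to BLAST output.
* Orthologous groups are inputs; the package does not cluster genes into
  OGs, and a gene belonging to two OGs is rejected rather than resolved.
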