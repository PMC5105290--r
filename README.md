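# phytophagr

Comparative genomics of phytophagous insect genomes, as a tidy R toolkit.

Genome projects for plant- and wood-feeding insects answer four recurring
comparative questions with one-off custom scripts: how widely conserved is
each gene across a panel of species; which genomic regions are bacterial
horizontal gene transfers (HGT) rather than conserved eukaryotic sequence;
which protein-domain families are expanded in the focal genome; and which
genes respond to a diet contrast. `phytophagr` implements these analyses as
tested, reusable, pipeable functions, plus simulators with known ground
truth so the whole pipeline can be validated end to end with no external
data.

Who it is for: comparative genomicists running multi-species gene-family
and HGT analyses who want the bespoke steps of such projects to be
reproducible, parameterized and unit-tested rather than re-scripted.

## The core computations

* **Three-set orthology partition** — species are split into three sets
  (default: five Coleoptera, five Lepidoptera/Diptera, five outgroup
  insects). An orthologous group (OG) counts in a set when it has genes
  from ≥ 2 of its species; genes are classified by their OG's span
  (three/two/one sets) with a single- vs multi-copy split for the
  widespread core, and OG-less genes fall back on homology: significant
  (E < 1e-5, strict) hits to other arthropod genes, to their own genome
  only, or to nothing (`classify_genes()`, `summarize_partition()`,
  `copy_number_split()`).
* **DNA-based HGT screen** — significant bacterial hits (E < 1e-5) merge
  into candidate regions; a region is excluded as a conserved gene iff its
  best overlapping animal E-value strictly beats the bacterial one;
  survivors are age-classified (≥ 90% identity recent; ≤ 80% with indels
  degrading), junction-confirmed across sequencing libraries, and annotated
  with flanking genes (`screen_hgt()` and friends). A compiled
  Smith–Waterman aligner with Karlin–Altschul E-values
  (E = K·m·n·e^(−λS)) supports fully self-contained runs
  (`local_align()`, `align_windows()`).
* **Domain-count expansions** — gene-level domain count matrices, the
  strict max-count > 5 expansion rule, per-species orthology-status bins,
  and focal-versus-mean enrichment ratios (`build_count_matrix()`,
  `flag_expansions()`, `enrichment_vs_mean()`).
* **Exact-test DE flagging** — a < 10-total-reads filter, quantile
  normalization, per-gene two-sided exact tests on condition-summed counts,
  Benjamini–Hochberg FDR, and strict |logFC| > 1 & adj-p < 0.05 flags
  (`run_de()`).
* **Simulators** — gene-family duplication/loss on a 15-species tree,
  planted bacterial insertions with junction evidence and decoy conserved
  genes, planted domain expansions, and negative-binomial count matrices,
  each emitting ground truth (`simulate_*()`).

See `vignettes/methods.Rmd` for the full model descriptions, parameter
defaults, numerical choices and limitations.

## A worked example

Simulate 500 gene families under duplication and loss, classify every gene,
and summarize:

```r
library(phytophagr)

sim <- simulate_gene_families(500, dup_rate = 0.3, loss_rate = 0.8, seed = 42)
cls <- classify_genes(sim$table, default_species_partition(),
                      arthropod_hits = sim$arthropod_hits,
                      self_hits = sim$self_hits, genes = sim$genes)
summ <- summarize_partition(cls, sim$table, default_species_partition())
summ$og
#> # A tibble: 4 × 2
#>   span      n_ogs
#>   <fct>     <int>
#> 1 three_set   214
#> 2 two_set     165
#> 3 one_set      99
#> 4 unshared      5
head(summ$superclass, 3)
#> # A tibble: 3 × 3
#>   species_id widespread universal_core
#>   <chr>           <int>          <int>
#> 1 AGAMB             196             17
#> 2 AGLAB             205             13
#> 3 AMELL             184             16
```

Of the 483 surviving families, 214 still span all three species sets; per
species, `widespread` counts its genes in those OGs and `universal_core`
the subset in OGs retaining all 15 species.

Plant bacterial insertions in a host genome, screen for them with the
built-in aligner, and tabulate the verdicts:

```r
hg <- simulate_hgt_genome(host_length = 80000, n_insertions = 5,
                          insertion_length = 800, divergence = 0.05,
                          n_decoys = 2, decoy_length = 600, seed = 42)
cand <- screen_hgt(
  align_windows(hg$genome, hg$windows, hg$bacterial_db, "bacterial"),
  align_windows(hg$genome, hg$windows, hg$animal_db, "animal"),
  junctions = hg$junctions)
glance(cand)
#> # A tibble: 1 × 6
#>   n_candidates n_retained n_excluded_conserved n_junction_confirmed n_recent
#>          <int>      <int>                <int>                <int>    <int>
#> 1            7          5                    2                    5        5
```

All five planted insertions are retained, junction-confirmed and
age-classified `recent` (~95% identity); both decoy conserved genes are
excluded because their animal E-value beats their bacterial one.

Fitted-object verbs follow broom conventions: `tidy()` gives per-gene or
per-candidate tibbles, `glance()` one-row summaries, and `autoplot()` /
`plot_domain_counts()` the standard figures (DE heatmap, stacked
domain-family bars, per-species category bars).

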