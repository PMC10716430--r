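# nitroplace

Gene-centric, phylogenetically informed quantification of the genetic
potential for nitrate ammonification versus denitrification in soil
metagenomes.

When soil microbes respire nitrate, the nitrite intermediate either
returns to the soil as ammonium (dissimilatory nitrate reduction to
ammonium, driven by the pentaheme nitrite reductase NrfA or its octaheme
homolog ONR) or leaves as gas through denitrification (nitrite reductases
NirK/NirS, then Nor and NosZ). Because the marker genes *nrfA*, *onr*,
*nirK* and *nirS* are typically single-copy, counting their read
fragments on a curated reference phylogeny — normalized per giga-base-pair
sequenced — yields a community-level index of nitrogen retention versus
loss potential:

```
δnrfA-nir = (nrfA − (nirK + nirS)) / Gbp
```

Positive δ means more genetic potential for NrfA-driven ammonification,
negative for denitrification.

The package is written for microbial ecologists working with phylogenetic
placement output (jplace) of functional-gene fragments. It provides:

* **Reference model**: newick trees with jplace `{N}` edge numbering,
  jplace v3/v1 readers and writers, and monophyletic gene-region labeling
  (`parse_newick()`, `read_jplace()`, `label_regions()`).
* **Motif screen**: curation rules for NrfA (five C-X-X-C-[H|K]
  heme-binding sites, interstitial histidine, canonical vs CXXCH-clade
  first site, calcium dependence) and ONR (eight sites,
  3x-CXXCH/1x-CXXCK/4x-CXXCH) — `scan_heme_sites()`,
  `classify_sequence()`, `dereplicate()`.
* **Placement classifier**: accumulates a read's likelihood-weight-ratio
  mass from tips to root until a threshold (default θ = 0.95) is reached,
  assigns the read to the gene region holding that edge, and discards
  reads with appreciable mass in two gene regions
  (`accumulate_read()`, `classify_reads()`, `count_genes()`).
* **Quantification**: per-Gbp normalization, δnrfA-nir, Kruskal-Wallis
  with rank-LSD/FDR compact letters, exact Wilcoxon-Mann-Whitney,
  Spearman correlations (`quantify_profiles()`, `group_compare()`).
* **Diversity**: abundance-weighted phylogenetic diversity (BWPD, θ = 1)
  and edge PCA of placement-mass imbalances (`bwpd()`, `edge_pca()`).
* **Validation**: in-silico fragmentation with sensitivity/specificity
  and decoy false-positive rates (`fragment_sequences()`,
  `confusion_metrics()`, `decoy_rate()`).
* **Genotype summaries**: co-occurrence of ammonification and
  denitrification genes in genome assemblies, including potential N2O
  producer/consumer categories (`classify_genotypes()`,
  `summarize_cohort()`).
* **Driver analysis**: Spearman collinearity pruning, random-forest
  tuning by out-of-bag RMSE, and accumulated local effects
  (`collinearity_filter()`, `tune_rf()`, `ale()`).
* **Synthetic data** with known ground truth for every stage
  (`simulate_refpkg()`, `simulate_placements()`, `simulate_metadata()`).

All user-facing functions take data frames first and return tibbles, so
the pipeline composes with the pipe; fitted objects have `tidy()` /
`glance()` methods and `autoplot()`s.

## Worked example

Simulate a reference package and one sample, classify its reads, and
compute δnrfA-nir:

```r
library(nitroplace)

rp  <- simulate_refpkg(c(nrfA = 8, onr = 4, nirK = 5, nirS = 5, outgroup = 4),
                       seed = 1)
sim <- simulate_placements(rp, c(nrfA = 60, onr = 5, nirK = 90, nirS = 40),
                           spread = 0.3, gbp = 2, seed = 2)
counts <- count_genes(sim$placements, rp$tree, rp$regions)
counts
#> # A tibble: 6 × 2
#>   label          count
#>   <chr>          <dbl>
#> 1 nrfA              60
#> 2 onr                5
#> 3 nirK              90
#> 4 nirS              40
#> 5 unassigned         0
#> 6 dual_discarded     0

get <- function(g) counts$count[counts$label == g]
delta_nrfa_nir(get("nrfA"), get("nirK"), get("nirS"), gbp = sim$gbp)
#> [1] -35
```

Every read lands in its true gene (no noise was leaked across regions),
and δ = (60 − 130)/2 = −35 counts Gbp⁻¹: the simulated community carries
more denitrification than ammonification potential.

Compare δ across biomes with planted offsets and read the compact letter
display (groups sharing a letter do not differ at α = 0.05):

```r
md  <- simulate_metadata(n = 120, seed = 3)$data
group_compare(md, "delta_nrfa_nir", "biome")
#> Kruskal-Wallis: H(3) = 67.37, p = 1.56e-14
#> # A tibble: 4 × 5
#>   group         n median mean_rank letters
#>   <chr>     <int>  <dbl>     <dbl> <chr>
#> 1 Cropland     33 -46.4       25.9 c
#> 2 Desert       21 -25.2       42.4 b
#> 3 Forest       29   7.91      84.4 a
#> 4 Grassland    37   4.23      82.9 a
```

Croplands sit far below forests and grasslands, as planted: the generator
gives croplands a −40 offset (heavy fertilization favors denitrifiers).

See `vignette("nitroplace-methods")` for the model, the accumulation
algorithm, the motif rules, and every numerical convention.

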