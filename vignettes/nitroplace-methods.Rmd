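---
title: "Methods: placement-based quantification of nitrate ammonifier vs denitrifier potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placement-based quantification of nitrate ammonifier vs denitrifier potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroplace)
library(dplyr)
```

## The scientific problem

When soil microorganisms use nitrate as an electron acceptor, two competing
fates await the nitrite intermediate: dissimilatory reduction to ammonium
(nitrate ammonification, DNRA), which retains nitrogen in the soil, or
denitrification, which loses it as gaseous compounds including the
greenhouse gas N2O. The ammonification step is catalyzed by the pentaheme
cytochrome c nitrite reductase NrfA (gene *nrfA*) or its octaheme homolog
ONR (*onr*); the competing denitrification step by the nitrite reductases
encoded by *nirK* or *nirS*. Because all four genes are typically
single-copy, counting their fragments in shotgun metagenomes — after
normalizing for sequencing depth — gives a community-level index of the
genetic potential for nitrogen retention versus loss.

`nitroplace` implements the full gene-centric, phylogenetically informed
workflow around that idea: curation of reference sequences by heme-motif
architecture, classification of placed metagenomic reads on a reference
phylogeny, depth-normalized gene counting and the δ*nrfA*-*nir* statistic,
placement-based diversity and ordination, in-silico validation of the
classifier, genotype co-occurrence summaries for genome assemblies, and
random-forest driver analysis with accumulated local effects. The package
does not compute phylogenetic placements itself: it consumes jplace files
produced upstream (e.g. by pplacer-based tools) together with a reference
tree, which keeps it independent of any particular placement engine.

## Reference model: tree, edge numbers, regions

All placement algebra happens in the coordinate system of a rooted
reference tree whose edges carry integer jplace numbers. Edges are
identified by their child node, oriented root-outward; branch lengths are
substitutions per site, zero allowed (some inference tools emit them) and
negative lengths rejected. When a newick string lacks `{N}` annotations,
edges are numbered deterministically in postorder starting at zero, so
synthetic fixtures are reproducible byte for byte.

A *gene region* is the edge set of the minimal clade spanning a gene's
reference tips — the clade's internal and pendant edges plus the edge
subtending it. The root carries no edge and belongs to no region. Target
regions (the genes being counted) must be pairwise edge-disjoint;
outgroup-role regions are carried for reporting only. These conventions
make "a read placed into the *nrfA* region" a well-defined, testable
predicate.

## Motif screen

Candidate NrfA/ONR peptides are screened by their heme c attachment
architecture. Heme-binding sites are C-X-X-C-[H|K] windows found by a
greedy left-to-right scan with non-overlap — a deterministic proxy for the
manual alignment inspection that a curator would perform. The rules are:

* **NrfA**: exactly five sites with a histidine strictly between sites 3
  and 4. A first-site C-X-X-C-K is the canonical form; C-X-X-C-H defines
  the CXXCH clade, a motif variant confined to a monophyletic bacterial
  lineage. Calcium independence is flagged by an Arg-His dipeptide in the
  segment between sites 3 and 4 ("X-X-Arg-His"); its His simultaneously
  satisfies the interstitial-His requirement.
* **ONR**: exactly eight sites in the pattern 3x-CXXCH, 1x-CXXCK,
  4x-CXXCH with a histidine between sites 6 and 7; always
  calcium-dependent.
* Anything else is non-target. `X` (unknown residue) never matches C, H,
  K or R, so partially masked sequences fail conservatively.

Only full-length classification is supported: fragments are validated
through the placement pipeline instead, mirroring how the two evidence
types are used in practice. When a sequence's motif flag and its tree
region disagree, the tree region is authoritative — the motif call is a
screening aid, not the final word.

## The accumulation classifier

A placed read arrives as up to seven (edge, likelihood-weight-ratio)
candidates. The classifier accumulates mass from the tips towards the
root: for each edge `e`, `S(e)` is the mass on `e` plus everything distal
to it, and the read's accumulated location is the edge *furthest from the
root* with `S(e) ≥ θ·M`, where `M` is the read's realized total mass and
`θ = 0.95` by default. Requiring `θ > 0.5` makes the qualifying edges a
single rootward chain, so the most distal one is unique and no tie-break
is ever needed. If no edge qualifies the read accumulates to the virtual
root and is reported with a root sentinel.

Two deliberate choices:

* **Relative thresholding.** Reported LWRs often sum to less than 1
  (placement mass loss). The threshold is taken relative to `M`, not to 1,
  so a read with 0.88 of 0.90 total mass on one tip still resolves there.
  An `relative = FALSE` switch compares against absolute mass instead.
* **Dual-gene discard.** A read whose accumulated edge falls outside every
  target region is discarded as ambiguous between two genes when at least
  two target regions each hold more than `(1 − θ)·M` of its mass — the
  minimal leak that could have prevented confinement to one gene at
  threshold θ. This operationalizes the rule of discarding reads with
  "mass as both genes"; the exact cutoff used historically is not
  documented, so ours is explicit and configurable. Reads failing the dual
  test are `unassigned` (this includes mass confined to outgroups).

Counting conserves reads exactly: per sample, gene counts plus unassigned
plus discarded equal the total read multiplicity.

## Quantification and comparisons

Counts are normalized per giga-base-pair sequenced. The headline statistic
is δ*nrfA*-*nir* = (*nrfA* − (*nirK* + *nirS*)) / Gbp: positive values
indicate greater genetic potential for NrfA-driven ammonification than for
denitrification. Gbp defaults to the raw sequencing total supplied in the
metadata; if a user prefers the total of the reads actually offered to
placement (e.g. trimmed forward reads), they simply supply that instead —
the statistic is agnostic to which convention the metadata encodes.

Between-biome differences use the tie-corrected Kruskal-Wallis H (from
`stats::kruskal.test`) followed by pairwise Fisher-LSD tests on mean
ranks: the t statistic divides the mean-rank difference by
`sqrt(S²·(N−1−H)/(N−k)·(1/nᵢ+1/nⱼ))` with `N−k` degrees of freedom, where
`S²` is the variance of all ranks. Pairwise p-values are
Benjamini-Hochberg adjusted and summarized by an insert-and-absorb compact
letter display. Letters are ordered by decreasing mean rank — the quantity
the LSD test actually compares — so the display can never contradict the
tests. Two-group contrasts (e.g. *nrfA* vs *nrfA*+*onr* within a biome)
use the Wilcoxon-Mann-Whitney test, exact when both groups have ≤ 25
observations without ties. Rank correlations are Spearman's ρ with average
ranks on ties; a constant vector is an error rather than a silent `NA`.

## Placement-based diversity

The abundance-weighted phylogenetic diversity of a sample's placement mass
is the one-parameter family

> BWPD(θ) = Σₑ ℓ(e) · (2·min(D(e), 1 − D(e)))^θ

with `D(e)` the normalized mass distal of edge `e`. θ = 1 is fully
abundance-weighted (the package default); θ = 0 counts the branch length
of every edge with mass on both sides, i.e. the classical PD of the
mass-spanning subtree, using the convention 0⁰ = 0 so one-sided edges drop
out. Mass is attached at each placement edge's distal node; the sub-edge
attachment position reported in jplace files is ignored, a second-order
simplification that slightly coarsens `D(e)` on the placement edge itself
but nowhere else.

Edge PCA ordinate samples by the per-edge mass imbalance
`2·D(e) − 1` on internal, non-root edges (pendant-edge imbalances are
redundant with their parent given normalization, and the root's imbalance
is fixed by it). Features are centered across samples and decomposed by
`prcomp`; loadings map back onto edges so each component reads as a set of
lineages. Samples with fewer than 20 placements are excluded by default —
imbalance estimates are dominated by sampling noise below that, which is
also where the reference tooling historically failed to compute.

## In-silico validation

Reference sequences are fragmented into fixed-length pieces (150 nt, or
50 aa — the longest peptide predictable from a 150 nt read) with uniform
source and offset sampling, error-free and seed-deterministic. Sensitivity
for gene `g` is the fraction of true-`g` fragments whose final pipeline
label is `g`; unplaced or misrouted fragments count against sensitivity.
Specificity is one minus the fraction of non-`g` fragments labeled `g`;
fragments that simply fail to place do not count against specificity. The
two are kept separate precisely because a gene can have < 100% sensitivity
with zero misassignments (the shortfall being unplaced fragments). Decoy
panels of distant multiheme cytochrome homologs are summarized by the
fraction placed at all and the fraction landing in a focal region.

## Genotype co-occurrence

For genome assemblies screened for *nrfA*/*onr*, denitrification potential
is counted by family: `nir` (= *nirK* ∨ *nirS*), *nor*, `nosZ` (= clade I
∨ clade II). "Complete denitrifier" is operationalized as all three
families present (the full nitrite-to-N2 pathway) — the term is not
formally defined in the literature we follow, so the assumption is stated
here. Potential N2O producers carry *nor* without *nosZ*; potential
consumers carry *nosZ* (alone or with *nir*/*nor*); the two are mutually
exclusive by construction and, together with `nir`-only carriers,
partition the assemblies that have any denitrification gene. Nitrate
reductases (*nar*/*nap*) are deliberately excluded from the count, and
*nosZ* clades are merged for the category logic but retained in the
output.

## Driver analysis

Environmental drivers of δ*nrfA*-*nir* are analyzed in three steps.
Collinear predictors are pruned first: pairs with |Spearman ρ| ≥ 0.7 are
joined into a graph and only the highest-priority variable of each
connected component is kept, with the priority list supplied by the user
(domain relevance cannot be automated). A random forest (`ranger`) is then
tuned by grid search over trees, features per split, and maximum tree
depth, selecting the lowest out-of-bag RMSE with ties broken towards
shallower trees and fewer features; one seed is fixed across all
candidates so the comparison is like-for-like. Variable selection, where
wanted, uses a documented stand-in — permutation-importance ranking with
elimination of variables whose importance is not positive across repeated
refits — rather than any specific published selection wrapper; the
variables to model can always be supplied directly.

Fitted models are visualized by first-order accumulated local effects:
the feature range is split at `grid_size = 30` quantile breakpoints,
per-interval mean prediction differences between interval endpoints are
accumulated, and the curve is centered so its interval-mass-weighted mean
is exactly zero. ALE only evaluates the model between the observed
endpoints of each interval, which keeps it honest under correlated soils
variables (unlike partial dependence). Categorical predictors (biome) get
one centered effect per level. Closed forms exist for linear and additive
predictors, and the tests hold the implementation to them.

## Synthetic data: what it emulates, and what it does not

Every stage is testable without external data through three generators.

* `simulate_refpkg()` builds a rooted tree with one coalescent-shaped
  clade per gene region hanging off the root — regions are monophyletic
  and disjoint by construction — plus reference peptides whose planted
  motif class matches each region.
* `simulate_placements()` draws reads per gene; each read's LWR vector is
  a symmetric Dirichlet draw (concentration 1/spread) over up to seven
  edges of its true region, so mass never leaves the region and the true
  label is recoverable. With probability `cross_region_rate` a read leaks
  `1 − θ + 0.01` of its mass into a foreign target region, which
  deterministically triggers the dual-gene discard — making the discard
  rate a direct binomial check of the planted rate.
* `simulate_metadata()` draws soil covariates uniformly within
  field-realistic continental-survey ranges (pH 4.0–9.6, nitrate
  1–59 mg kg⁻¹, organic carbon 0.1–5.9%, ...) and builds the response as
  planted partial effects plus biome offsets plus Gaussian noise
  (default sd 10 counts Gbp⁻¹, chosen to give the fitted forests an
  R² in the 0.5–0.8 range typical of field soil models). The default
  planted effect is a saturating increase with log(SOC/nitrate), the
  electron donor/acceptor balance expected to favor ammonifiers.

What the generators do **not** emulate: sequence evolution along the tree
(placement noise is statistical, not phylogenetic), sequencing error,
compositional coupling between genes, spatial autocorrelation of soil
variables, or realistic biome frequencies. Passing tests therefore
demonstrate algorithmic correctness — conservation, calibration, exact
recovery in noise-free regimes, statistical behavior under planted
effects — not field performance on real metagenomes, which additionally
depends on the quality of the reference phylogeny and the upstream
placement engine.

## Numerical choices and problem sizes

Tolerances: LWR sums may exceed 1 by 1e-6 (parser); mass-profile
normalization checked at 1e-6; accumulation and dual-discard comparisons
use a 1e-12 slack so ties at the threshold qualify; ALE centering is exact
to floating point. Degenerate inputs fail loudly: empty placement lists,
θ ≤ 0.5, gbp ≤ 0, constant vectors in correlations and ALE, single-group
comparisons, regions whose spanning clades overlap.

The test-suite problem sizes were chosen to keep the whole suite around a
minute on one CPU while leaving no property undersampled: 1000 random
trees (≤ 64 tips) for the accumulation oracle, 1000 reads for the
discard-rate calibration, 500 sequences per motif class, 200 null
replicates for the letter-display type-I check, and 10 simulations of 250
samples for planted-effect recovery by the random forest.

## A worked example

```{r example}
rp <- simulate_refpkg(c(nrfA = 8, onr = 4, nirK = 5, nirS = 5, outgroup = 4),
                      seed = 1)
sim <- simulate_placements(rp, c(nrfA = 60, onr = 5, nirK = 90, nirS = 40),
                           spread = 0.3, gbp = 2, seed = 2)
counts <- count_genes(sim$placements, rp$tree, rp$regions)
counts
get <- function(g) counts$count[counts$label == g]
delta_nrfa_nir(get("nrfA"), get("nirK"), get("nirS"), gbp = sim$gbp)
```

The negative δ says this simulated community holds more denitrification
than ammonification potential — as planted.

## Known limitations

* jplace `distal_length`/`pendant_length` are parsed but not used; masses
  attach at whole edges.
* The dual-discard epsilon is a documented convention, not a reproduction
  of any specific historical cutoff.
* BWPD follows the published one-parameter formula; alternative tool
  implementations may normalize pendant contributions differently.
* The motif screen assumes full-length, unaligned amino-acid input;
  fragment-level evidence must come from placement, not motifs.
* Edge PCA restricts features to internal edges; tools that include
  pendant edges will produce rotated but compositionally equivalent
  ordinations.
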