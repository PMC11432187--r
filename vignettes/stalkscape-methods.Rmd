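---
title: "Methods: spatiotemporal stalk transcriptomics and SELEX promoter scanning"
author: "stalkscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal stalk transcriptomics and SELEX promoter scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

Grass stalks elongate internode by internode, and the internodes of one
stalk span a developmental gradient: basal internodes have finished
growing while mid-stalk internodes elongate rapidly and deposit secondary
cell wall. Sampling every internode of stalks at several ages gives a
spatiotemporal grid of transcriptomes — in the emulated design, 19
internodes across four stages (1 + 3 + 6 + 9 internodes, bottom to top),
each in two biological replicates.

`stalkscape` implements the full downstream analysis of such a design:

1. **Expression I/O** — TPM matrices, replicate agreement, collapsing
   replicates to internode means, `log2(TPM + 1)` transformation.
2. **High-variation genes and structure** — MAD-based HVG selection,
   developmental-zone assignment of internodes, fuzzy c-means expression
   clusters.
3. **Weighted co-expression network** — soft threshold, topological
   overlap, module detection, module eigengenes, module–trait statistics,
   hub genes.
4. **TF families** — HVTF ratios per family, expression groups, family
   overrepresentation.
5. **SELEX** — 10-mer enrichment of selection rounds against a shuffled
   null, seed-based PWM construction, motif fold change.
6. **Promoter scanning** — genome-wide affinity tracks from the 10-mer
   table, strand-aware promoter windows, high-affinity site calls.
7. **Synthetic data** — generators for every input with known ground
   truth, used by the tests and the acceptance script.

All heavy inputs are synthetic: the generators in `R/simulate.R` stand in
for the deposited study data, so every claim the package's tests make is
a parameter-recovery claim about planted truth, not a reproduction of the
original measurements.

# Transcriptome models and choices

## Scale and replicate handling

All downstream analyses operate on `log2(TPM + 1)` of the
replicate-collapsed 19-column matrix. The offset of 1 is the conventional
choice for TPM and keeps zeros at zero. Replicate agreement is quantified
by the Pearson correlation of the two replicate columns of each internode
on the log scale; Pearson (not Spearman) is used because the log
transform already tames the dynamic range. Replicates are collapsed by
the arithmetic mean on the scale of the stored matrix.

## HVG selection

A gene's variation score is the unscaled median absolute deviation across
the 19 internode columns, `MAD(g) = median_j |x_gj - median_j x_gj|`,
with the default cutoff `MAD > 1` on the log2 scale. The 1.4826
normal-consistency factor is deliberately omitted: the cutoff is a
filter, not a variance estimate, and the plain definition is the one the
cutoff value refers to.

## Developmental zones

Internode columns are clustered by average-linkage hierarchical
clustering on the Euclidean distance between per-gene standardized
profiles and cut into `k = 4` groups. Zone labels I–IV are assigned by
the mean developmental stage of each group's internodes (ties broken by
mean position along the stalk ordering), so Zone I is always the earliest
material. A PCA of the same matrix reports per-component variance
fractions; on simulated data PC1+PC2 carry most of the variance because
four zone archetypes dominate.

## Fuzzy c-means

Gene profiles are standardized per gene and clustered with standard fuzzy
c-means: centroids `v_i = sum_g u_gi^m x_g / sum_g u_gi^m`, memberships
`u_gi = 1 / sum_k (d_gi/d_gk)^(2/(m-1))`, iterated until the largest
membership change falls below `tol = 1e-6` (at most 200 iterations). The
fuzzifier defaults to the dimension-based heuristic of Schwämmle and
Jensen (for 19 samples and a few thousand genes this gives m ≈ 1.1). A
gene coinciding exactly with a centroid takes membership 1 there. The
objective `sum u^m d^2` is non-increasing across iterations and is
asserted in the tests. Initial memberships are random from a mandatory
seed; because c-means with many clusters is prone to local optima, the
fit restarts `nstart = 5` times and keeps the lowest final objective — on
planted 12-archetype data single starts occasionally merge two clusters
(objective roughly 5x higher), which the restart reliably repairs.

# The co-expression network

The network is implemented from first principles rather than wrapping an
existing package, so every step is testable against brute-force oracles.

**Adjacency.** Unsigned: `a_ij = |cor(x_i, x_j)|^beta`. The unsigned form
is the historical default for correlation-based adjacency. Constant genes
have their correlations set to 0 with a warning.

**Soft threshold.** `power_scan()` reports, per candidate power, the
scale-free fit R² (squared correlation of `log10 freq(k)` vs `log10 k`
over 10 logarithmic connectivity bins) and the mean connectivity, and
picks the smallest power with R² > 0.85 and mean connectivity below a
cutoff. The cutoff of 100 refers to a transcriptome-scale network of
roughly 20,000 genes and is rescaled proportionally for smaller gene sets
(`scale_k_max()`). On block-structured synthetic data the degree
distribution is not scale-free — a handful of planted modules gives a
bimodal connectivity distribution — so the scan may legitimately find no
qualifying power; analyses then fall back to the default `beta = 9`.

**Topological overlap.**
`TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
`l_ij = sum_u a_iu a_uj` (u ≠ i, j) and `k_i` the connectivity. The
implementation is a matrix product; the tests compare it to a literal
triple-loop evaluation to 1e-12 on 20-gene matrices.

**Module detection.** Average-linkage clustering of `1 - TOM`, cut at a
static height (default 0.99 of the maximum merge height); branches of at
least `min_module_size = 50` genes become modules, named with the
conventional color series by decreasing size. Two refinements follow,
both driven by the same membership criterion (mean TOM of a gene to a
module at least `member_frac = 0.5` of the module's median intramodular
TOM): members failing it are moved to the grey pool, and unassigned genes
passing it for some module are adopted. The pruning step matters at small
sample counts: with 19 samples a noise gene chance-correlates with a
large module at |r| ≈ 0.5–0.7 often enough that, through the
shared-neighbor term of TOM, tens of background genes would otherwise
attach to every large branch. This is a simplified form of the dynamic
hybrid tree cut — a static split plus proximity-based reassignment —
and no claim is made that it reproduces the reference implementation's
branch heuristics. Modules are not merged by eigengene similarity;
`member_frac` and the cut height are exposed.

**Module eigengene.** The first right singular vector of the
gene-standardized module submatrix (samples as observations), sign-fixed
to correlate positively with the module's mean profile; a near-zero mean
profile falls back to alignment with the first gene, and a rank-0 module
yields a zero vector with a warning. The eigengene equals the leading
eigenvector of the sample-space covariance, which the tests verify
against a full eigendecomposition.

**Module–trait statistics.** Pearson r between eigengenes and traits with
the two-sided Student transform `t = r sqrt((n-2)/(1-r^2))` on n − 2
degrees of freedom; the tests check the analytic p against a 10,000-draw
permutation null at n = 19. Module membership (gene vs own eigengene) and
gene significance (gene vs trait) use plain Pearson correlations.

**Hubs.** Intramodular connectivity is the row sum of TOM within the
module; the hub network keeps the top-100 genes plus any flagged genes
(e.g. TFs and their candidate targets) and the edges above the 0.95
weight quantile.

# TF-family analysis

Family ratios divide each family's HVTF count by its TF count; the
global fraction is reported alongside. HVTF expression groups are
average-linkage hierarchical clusters of standardized profiles cut at
k = 6, with group ids ordered by the mean peak position for stable
naming. Overrepresentation of a family within a group is the one-sided
hypergeometric tail against the family's count among all grouped HVTFs —
chosen as the standard enrichment test where none is otherwise specified
— with Benjamini–Hochberg q-values; the implementation is checked against
exhaustive enumeration on small tables.

# SELEX analysis

**Counting.** All 10-mer windows of all reads are counted on both strands
("double-strand" counting: ligands are double-stranded), so a word and
its reverse complement always carry identical counts and scores. Counting
is exact and compared to a naive substring scan in the tests.

**Null and enrichment.** The null library is the selected library with
each read's bases independently permuted — a mononucleotide shuffle that
preserves length and per-read composition exactly (a dinucleotide-
preserving option exists). Enrichment is the pseudocounted frequency
ratio `(f_sel + eps)/(f_null + eps)` with `eps` one window per library,
i.e. a (count + 1) ratio at equal depth. Because enrichment normalizes by
library size, the null can be deepened at will: analyses shuffle each
read `times = 20` times, which shrinks the sampling noise of the null
frequencies twentyfold at no cost to the selected-side signal. At a
sequencing depth of 20,000 reads the per-k-mer counting noise is the
limiting factor for replicate comparisons; `enrichment_replicate_cor()`
therefore restricts to k-mers with at least 30 selected-library counts in
both replicates, below which Poisson noise is comparable to the affinity
signal.

**Deduplication.** `dedupe_reads()` removes exact-sequence duplicates, the
standard QC step for sequenced SELEX libraries where identical reads are
presumed PCR copies. The simulator, however, models no PCR: duplicate
reads in simulated libraries are genuine abundance (independent draws
from the selected pool), so the simulated analyses count libraries as
sequenced and deduplication is exercised on constructed fixtures instead.

**Motif construction.** The seed is a locally maximal enriched 10-mer (no
single-substitution neighbor scores higher); distinct planted motifs
yield distinct local maxima. Core PWM columns score each base by the
enrichment of the seed with that position substituted — the shuffled-null
denominator corrects each variant for its background abundance — and
`extend` flanking columns are tallied from seed-aligned reads, corrected
by the null base composition. Columns are normalized and a per-column
IUPAC consensus is called from all bases reaching 25% of the column. The
match threshold for fold-change counting defaults to log-odds 0 against
the null library's base composition; the fold change is the pseudocounted
ratio of matching positions between selected and null libraries, with a
depth correction when they differ in size.

# Promoter scanning

The genome track assigns every position the larger of the forward and
reverse-complement enrichment of its 10-mer (windows containing N score
0); reverse-complementing the genome exactly reverses the track.
Promoters are the 2 kb adjacent to the TSS on the upstream side of the
gene's strand — `[tss - 2000, tss)` for `+` genes and `[tss, tss + 2000)`
for `-` genes in 0-based half-open coordinates, clipped to chromosome
bounds; because "TSS + 2 kb" is ambiguous in general usage, a
`mode = upstream|downstream|both` switch is provided. GFF3 input is
1-based, BED output 0-based half-open; the conversion is unit-tested
explicitly.

Site calling emits positions inside promoter windows whose score strictly
exceeds the genome-wide quantile of the track (default 0.999), merging
overlapping above-threshold runs to their local maximum and annotating
each site with its gene and signed TSS distance. A quantile threshold has
a built-in operating characteristic worth stating plainly: about 0.1% of
*all* genome positions exceed the 0.999 quantile by construction, so on a
1 Mb genome whose promoters cover 4% of the sequence, a few dozen
above-threshold promoter positions are expected from measurement noise
alone, independent of how clean the enrichment table is. Calls at the
default quantile are therefore a sensitive first pass, not a specific
one; `rank_promoters()` — the maximum track score per promoter — is the
robust statement and is what separates planted target promoters from all
others in the end-to-end tests.

# The synthetic-data generators

## Expression, zones, clusters, traits

Each planted gene is `baseline + amplitude * archetype + noise` on the
log2 scale, exported as linear TPM (`2^x - 1`, clipped at 0). Defaults,
chosen once to emulate the study conditions:

* 19 internodes × 2 replicates in the 1/3/6/9 stage design; zone map
  I = the four earliest internodes, II = six basal, III = seven upper,
  IV = the two fast-elongating mid-stalk internodes.
* 12 cluster archetypes: zone-level weight patterns (four distinct values
  per cluster) plus a small smooth positional component (amplitude 0.35)
  that keeps the twelve archetypes mutually distinguishable while leaving
  the columns zone-dominated; all archetypes have MAD ≥ 0.5 after
  standardization so that amplitude 2.5 puts planted genes above the
  HVG cutoff.
* per-replicate noise SD 0.3 on the log2 scale, calibrated so replicate
  correlations exceed 0.97 (baseline SD 1.5 across genes dominates the
  shared signal);
* traits: internode length couples to the Zone-IV elongation archetype
  with population r = 0.9 and diameter to the monotone bottom-to-top
  archetype with r = 0.87, via `trait = r z + sqrt(1-r^2) noise` before
  rescaling to cm/mm units with a positivity floor.
* the three module archetypes used for network recovery are near-
  orthogonal (max |cor| = 0.16) by design: an unsigned network cannot
  distinguish strongly anti-correlated blocks — `|cor|^beta` maps both
  to high adjacency — so planting ±correlated archetypes would test the
  generator, not the detector. The 12-cluster emulation intentionally
  keeps ±correlated archetypes, and its network run shows the expected
  merging; the vignette of results treats that as a property of unsigned
  networks, not a defect.

## SELEX

A pool of 30 × 20,000 random 101-mers stands in for the synthesized
initial library; each round resamples the pool (with replacement, i.e.
multinomially) with weights `occupancy^round`, where occupancy is a
logistic function of the best-window log-odds score against the hidden
PWM on either strand. Two emulation details matter:

* the hidden PWM is per-column **heterogeneous** (consensus probabilities
  0.58–0.97). With a homogeneous PWM all single-mismatch variants share
  one true affinity and replicate enrichment tables cannot correlate
  beyond sampling noise; real TF motifs have unequal column information,
  and that gradient is what the replicate-agreement statistic measures.
* replicate experiments share the pool (`pool_seed`) and draw their
  selections independently — as in the wet protocol, where biological
  replicates share the one synthesized ligand library. Pool composition
  (which molecules carry which flanks) is then common signal.

The logistic midpoint sits `occupancy_margin = -0.5` scale units above
the mean single-mismatch score with scale `tau = 2`, placing the
consensus on the steep part of the curve so mismatch classes are graded
rather than saturated; four rounds then enrich the consensus frequency
monotonically and leave it the top-ranked 10-mer.

## Genome

1 Mb of i.i.d. background with 20 genes in jittered slots on random
strands; the consensus is planted at a known offset 50–1950 bp upstream
of the TSS in the first three promoters. Chance background occurrences of
the consensus or any single-mismatch variant (either strand) are removed
by local redrawing, so the planted instances are the only motif sites and
truth BED coordinates are exact.

## What the generators do not emulate

No negative-binomial count noise, library-size variation or batch
structure on the expression side; no PCR bias, sequencing error or
adapter contamination on the SELEX side; no repeat structure, GC
heterogeneity or gene-density variation in the toy genome. Passing the
recovery tests therefore demonstrates correctness of the algorithms under
clean planted signal, not robustness to every artifact of real data.

# Problem sizes and determinism

Test and acceptance runs use 1,500–3,600 genes, 19 internodes, 20,000
reads per SELEX round and a 1 Mb genome — sizes at which the full suite
runs in minutes on one core while keeping every recovery quantity
well-resolved. Every stochastic step takes an explicit seed; generators
save and restore the caller's RNG state, and reruns are byte-identical
(asserted for the pipeline outputs).

# Known limitations

* The dynamic tree cut is a simplified hybrid (static height plus
  membership pruning/adoption); module counts on real data will differ
  from the reference implementation's.
* The unsigned network merges anti-correlated gene sets by construction;
  a signed variant is not implemented.
* Quantile-based site calling fixes the genome-wide false-positive rate
  rather than the promoter-level one (see above); promoter ranking is
  provided for specificity.
* The SELEX simulator's finite pool caps per-k-mer carrier counts;
  enrichment magnitudes are meaningful relatively, not as binding
  constants.
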