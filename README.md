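# stalkscape

Spatiotemporal analysis of grass stalk internode transcriptomes, and the
regulatory follow-up that connects a transcription factor to its target
promoters — as one tested R package.

Grass stalks grow internode by internode, so the internodes of a single
stalk form a developmental series: basal internodes are mature while
mid-stalk internodes elongate rapidly and synthesize secondary cell wall.
Given TPM expression for every internode of stalks at several ages (here:
19 internodes across four stages, two replicates each), `stalkscape`

* selects high-variation genes by unscaled median absolute deviation,
  `MAD(g) = median_j |x_gj − median_j x_gj| > 1` on log2(TPM+1);
* assigns internodes to developmental zones (hierarchical clustering of
  standardized columns, cut at k = 4, labels ordered by stage) and reports
  the PCA variance structure;
* partitions HVGs into fuzzy c-means expression clusters
  (`u_gi = 1 / Σ_k (d_gi/d_gk)^{2/(m−1)}`, fuzzifier from the standard
  dimension-based heuristic, seeded multi-start);
* builds a weighted co-expression network from scratch: unsigned
  adjacency `a_ij = |cor(x_i,x_j)|^β` with β chosen by scale-free fit
  (R² > 0.85, mean connectivity criterion), topological overlap
  `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, module detection by
  average-linkage tree cutting with TOM-membership pruning, module
  eigengenes (first PC of the module submatrix), module–trait Pearson
  correlations with Student-t p-values, and top-connectivity hub networks;
* summarizes transcription-factor families over the HVGs and tests family
  overrepresentation in expression groups (hypergeometric + BH);
* analyses HT-SELEX rounds: double-stranded 10-mer counting, enrichment
  against a composition-preserving shuffled null
  `(f_sel + ε)/(f_null + ε)`, locally-maximal seeds, substitution-based
  PWM construction with IUPAC consensus, motif fold change;
* scans a genome with the 10-mer enrichment table (per-position
  best-strand score), extracts strand-aware TSS±2kb promoter windows from
  GFF3, calls high-affinity sites above a genome-wide score quantile and
  ranks promoters by best site.

Because the original sequencing data are not required, a first-class
synthetic-data module generates every input with known ground truth — a
19-internode expression matrix with planted zones, clusters and modules,
trait vectors with planted couplings, SELEX libraries evolved from a
hidden PWM, and a 1 Mb toy genome with motif instances planted in three
promoters — so the whole pipeline is verified end to end by parameter
recovery.

## Worked example

The `analysis/` directory holds the numbered drivers (simulate → zones
and clusters → TF families → network → SELEX → promoter scan). A
condensed session:

```r
library(stalkscape)

cfg <- sim_config(seed = 42)
simulate_all(cfg, "data")                      # writes TSV/FASTA/GFF3 inputs

expr <- read_expression("data/expr.tsv")
meta <- read_sample_meta("data/meta.tsv")
min(replicate_correlation(expr, meta)$r)
#> [1] 0.9810289

logm <- log_transform(collapse_replicates(expr, meta), offset = 1)
hv   <- select_hvgs(logm, cutoff = 1)          # 3198 of 3600 genes
za   <- assign_zones(logm[hv$gene_ids, ], k = 4)
table(za$zones)
#>   I  II III  IV
#>   4   6   7   2
```

The four zones are the planted developmental zones (the two Zone-IV
internodes are the fast-elongating mid-stalk ones), recovered exactly at
the calibrated noise level. Downstream, the network run
(`analysis/04_coexpression_network.R`) detects the planted modules and
reports, e.g.

```
diameter: best module blue, r = 0.81 (p = 3.1e-05)
```

and the SELEX driver (`analysis/05_selex_motifs.R`) prints the enrichment
table whose top word is the hidden consensus:

```
       kmer count_sel count_null enrichment
 ACCTAACTTG      2216         61   715.1613
 CAAGTTAGGT      2216         61   715.1613   # its reverse complement
frequency of ACCTAACTTG by round: 8.15e-07 -> 1.52e-05 -> 8.56e-05 -> 0.000273 -> 0.000602
replicate log-enrichment correlation: r = 0.927 over 3314 k-mers
```

The promoter scan (`analysis/06_promoter_scan.R`) then ranks the three
promoters carrying planted sites above all 17 others:

```
 gene_id max_score
    TG01 715.16129
    TG02 715.16129
    TG03 715.16129
    TG06  50.26316
```

`vignettes/stalkscape-methods.Rmd` documents every model, default and
design decision, including what the generators do and do not emulate.

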