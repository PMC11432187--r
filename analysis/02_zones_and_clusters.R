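#!/usr/bin/env Rscript
# Spatiotemporal transcriptome structure: replicate agreement, HVG
# selection (MAD > 1 on log2(TPM+1)), developmental-zone assignment by
# hierarchical clustering + PCA, and fuzzy c-means clustering of the HVGs
# into 12 expression clusters.
#
# Reads data/ (from 01_simulate_data.R); writes results/02_*.

library(stalkscape)

dir.create("results", showWarnings = FALSE)
expr <- read_expression("data/expr.tsv")
meta <- read_sample_meta("data/meta.tsv")

rc <- replicate_correlation(expr, meta)
write.table(rc, "results/02_replicate_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("replicate correlation: min r = %.3f (all %d internodes > 0.97: %s)",
                min(rc$r), nrow(rc), all(rc$r > 0.97)))

logm <- log_transform(collapse_replicates(expr, meta), offset = 1)
hv <- select_hvgs(logm, cutoff = 1)
write.table(data.frame(gene = names(hv$mad), mad = hv$mad,
                       hvg = names(hv$mad) %in% hv$gene_ids),
            "results/02_hvgs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("HVGs: %d of %d genes with MAD > 1", length(hv$gene_ids),
                nrow(logm)))
hm <- logm[hv$gene_ids, ]

za <- assign_zones(hm, k = 4)
write.table(data.frame(internode = names(za$zones), zone = za$zones),
            "results/02_zones.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("zones: %s", paste(sprintf("%s=%d", names(table(za$zones)),
                                           table(za$zones)), collapse = " ")))
message(sprintf("PC1+PC2 explain %.1f%% of sample variance",
                100 * sum(za$pca_variance_explained[1:2])))

fc <- fuzzy_cmeans(hm, c = 12, seed = 7)
write.table(data.frame(gene = names(fc$hard_labels), cluster = fc$hard_labels,
                       max_membership = round(apply(fc$membership, 1, max), 4)),
            "results/02_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
prof <- cluster_mean_profiles(fc, hm)
write.table(data.frame(cluster = rownames(prof), round(prof, 4)),
            "results/02_cluster_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("fuzzy c-means: %d clusters, fuzzifier m = %.3f, sizes %s",
                fc$c, fc$fuzzifier,
                paste(sort(table(fc$hard_labels), decreasing = TRUE),
                      collapse = "/")))

# against the generator's truth, where available
truth_file <- "data/truth/truth.json"
if (file.exists(truth_file)) {
  truth <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
  zone_truth <- unlist(truth$zone)
  message(sprintf("zone assignment matches planted zones: %s",
                  identical(za$zones[names(zone_truth)], zone_truth)))
}
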