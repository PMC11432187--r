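#!/usr/bin/env Rscript
# Weighted co-expression network over the HVGs: soft-threshold scan,
# topological overlap, module detection, module eigengenes, module-trait
# correlation (internode length and diameter) and the hub network of the
# best length-associated module.
#
# Reads data/; writes results/04_*.
#
# Problem size note: the simulated matrix (a few thousand genes) keeps the
# dense TOM comfortably in memory; for genome-scale inputs run the scan on
# the MAD-filtered gene set as the study did.

library(stalkscape)

dir.create("results", showWarnings = FALSE)
expr <- read_expression("data/expr.tsv")
meta <- read_sample_meta("data/meta.tsv")
traits <- read_traits("data/traits.tsv")

logm <- log_transform(collapse_replicates(expr, meta), offset = 1)
hv <- select_hvgs(logm, cutoff = 1)
hm <- logm[hv$gene_ids, ]

ps <- power_scan(hm, betas = 1:14, k_max = scale_k_max(nrow(hm)))
write.table(ps$table, "results/04_power_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
beta <- if (is.na(ps$beta)) 9 else ps$beta
message(sprintf("power scan: chosen beta = %s (R2 > %.2f, mean k < %.1f)%s",
                beta, ps$r2_min, ps$k_max,
                if (is.na(ps$beta)) " [no power met both criteria; default 9]" else ""))

adj <- adjacency_matrix(hm, beta = beta)
tom <- compute_tom(adj)
labels <- detect_modules(tom, min_module_size = 50)
write.table(data.frame(gene = names(labels), module = labels),
            "results/04_modules.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tab <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
message(sprintf("modules: %d (+%d genes unassigned): %s", length(tab),
                sum(labels == "grey"),
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))

mes <- module_eigengenes(hm, labels)
write.table(data.frame(module = rownames(mes), round(mes, 5)),
            "results/04_eigengenes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mt <- module_trait(hm, mes, traits, labels)
write.table(mt$stats, "results/04_module_trait.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mt$mm, "results/04_module_membership.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (tr in unique(mt$stats$trait)) {
  s <- mt$stats[mt$stats$trait == tr, ]
  b <- s[which.max(abs(s$r)), ]
  message(sprintf("%s: best module %s, r = %.2f (p = %.2g)", tr, b$module,
                  b$r, b$p))
}

best_len <- with(mt$stats[mt$stats$trait == "length", ],
                 module[which.max(abs(r))])
hn <- hub_network(tom, labels, best_len,
                  top_n = min(100, sum(labels == best_len)))
write.table(hn$edges, "results/04_hub_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(hn$nodes, "results/04_hub_nodes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("hub network of %s: %d nodes, %d edges; top hub %s",
                best_len, nrow(hn$nodes), nrow(hn$edges),
                hn$nodes$gene[which.max(hn$nodes$connectivity)]))

# expression correlation of annotated TFs in the module with its hubs
ann_file <- "data/tf_families.tsv"
if (file.exists(ann_file)) {
  ann <- read_tf_annotation(ann_file)
  tfs <- intersect(ann$gene_id, names(labels)[labels == best_len])
  targets <- head(hn$nodes$gene, 5)
  if (length(tfs) && length(targets)) {
    gg <- gene_gene_correlation(hm, tfs, targets)
    write.table(gg, "results/04_tf_target_correlation.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
    message(sprintf("TF-target correlations in %s: %d pairs, %d with r > 0.9",
                    best_len, nrow(gg), sum(gg$r > 0.9)))
  }
}
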