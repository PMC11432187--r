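#!/usr/bin/env Rscript
# Transcription-factor view of the high-variation genes: per-family HVTF
# ratios, six expression groups of the HVTFs, and family
# overrepresentation per group (hypergeometric, BH-adjusted).
#
# Reads data/; writes results/03_*.

library(stalkscape)

dir.create("results", showWarnings = FALSE)
expr <- read_expression("data/expr.tsv")
meta <- read_sample_meta("data/meta.tsv")
ann <- read_tf_annotation("data/tf_families.tsv")

logm <- log_transform(collapse_replicates(expr, meta), offset = 1)
hv <- select_hvgs(logm, cutoff = 1)

fr <- family_ratios(hv, ann)
write.table(fr$table, "results/03_tf_ratios.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("HVTFs: %d of %d TFs (%.1f%%)", sum(fr$table$n_hvtfs),
                sum(fr$table$n_tfs), 100 * fr$global_fraction))
message(sprintf("highest-ratio families: %s",
                paste(head(fr$table$family, 3), collapse = ", ")))

hvtfs <- intersect(ann$gene_id, hv$gene_ids)
groups <- group_hvtfs(logm[hvtfs, ], k = 6)
write.table(data.frame(gene = names(groups), group = groups),
            "results/03_tf_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("HVTF groups: %s",
                paste(sprintf("%s=%d", names(table(groups)), table(groups)),
                      collapse = " ")))

enr <- family_overrepresentation(groups, ann)
write.table(enr, "results/03_tf_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- enr[enr$q < 0.05, ]
message(sprintf("overrepresented (q < 0.05): %d family-group pairs%s",
                nrow(sig),
                if (nrow(sig)) paste0(" (top: ", sig$family[1], " in ",
                                      sig$group[1], ")") else ""))
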