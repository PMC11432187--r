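#!/usr/bin/env Rscript
# Generate the synthetic study data set: 19 stalk internodes x 2 replicates
# of TPM expression with 12 planted clusters over 4 developmental zones,
# internode traits coupled to planted archetypes, a TF-family annotation,
# four SELEX selection rounds from a hidden MYB-like PWM, and a 1-Mb toy
# genome with the consensus planted in three promoters.
#
# Writes data/ (pipeline inputs) and results/01_truth summaries.

library(stalkscape)

seed <- 42
dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = seed)
message("simulating full data set (seed ", seed, ") into data/ ...")
paths <- simulate_all(cfg, "data")

sim_meta <- read_sample_meta(paths$meta)
message(sprintf("expression: %d genes x %d samples (%d internodes)",
                nrow(read_expression(paths$expr)), nrow(sim_meta),
                length(unique(sim_meta$internode))))
message(sprintf("SELEX: rounds 0..%d, %d reads each", cfg$rounds,
                cfg$reads_per_round))
message(sprintf("genome: %.1f kb, %d genes, %d planted promoter sites",
                cfg$genome_length / 1000, cfg$n_genes_annotated,
                cfg$n_planted_sites))
message("inputs written under data/; ground truth under data/truth/")
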