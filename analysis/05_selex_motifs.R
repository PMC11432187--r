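#!/usr/bin/env Rscript
# SELEX regulatory analysis: 10-mer enrichment of the final selection
# round against its composition-preserving shuffle, seed detection, PWM
# construction, motif fold change, and replicate agreement between two
# selections from the shared ligand pool.
#
# Reads data/r*.fasta; writes results/05_*.

library(stalkscape)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 42)          # matches 01_simulate_data.R
rounds <- 0:cfg$rounds
libs <- lapply(rounds, function(r)
  read_selex_reads(sprintf("data/r%d.fasta", r), round = r))

sel <- libs[[length(libs)]]
null <- shuffle_library(sel, seed = 1042, times = 20)
ke <- kmer_enrichment(sel, null, k = 10)
tk <- top_kmers(ke, 1000)
write.table(tk, "results/05_kmers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top 10 enriched 10-mers:")
print(head(tk, 10), row.names = FALSE)

# enrichment trajectory of the top word across rounds
topw <- tk$kmer[1]
freq <- vapply(libs, function(l) {
  cs <- library_kmer_counts(l, 10)
  cs$counts[kmer_to_code(topw) + 1] / cs$total
}, numeric(1))
write.table(data.frame(round = rounds, frequency = freq),
            "results/05_top_kmer_trajectory.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("frequency of %s by round: %s", topw,
                paste(signif(freq, 3), collapse = " -> ")))

seeds <- find_seeds(ke, n = 3)
message(sprintf("locally maximal seeds: %s", paste(seeds, collapse = ", ")))
mo <- build_motif(ke, sel, null)
write_meme(mo, "results/05_motif.meme")
write.table(data.frame(base = rownames(mo$pwm), round(mo$pwm, 4)),
            "results/05_motif_pwm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("motif: seed %s, consensus %s", mo$seed, mo$consensus))
fold <- motif_fold_change(mo, sel, null)
message(sprintf("motif fold change (selected vs shuffled): %.2f",
                as.numeric(fold)))

# an independent replicate selection from the same synthesized pool
sx2 <- simulate_selex(cfg, seed = cfg$seed + 26L)
sel2 <- sx2$libraries[[cfg$rounds + 1L]]
null2 <- shuffle_library(sel2, seed = 2042, times = 20)
ke2 <- kmer_enrichment(sel2, null2, k = 10)
r <- enrichment_replicate_cor(ke, ke2)
message(sprintf("replicate log-enrichment correlation: r = %.3f over %d k-mers",
                as.numeric(r), attr(r, "n")))
write.table(data.frame(statistic = "replicate_log_enrichment_r",
                       value = as.numeric(r), n_kmers = attr(r, "n")),
            "results/05_replicate_agreement.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
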