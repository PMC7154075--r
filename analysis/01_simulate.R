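#!/usr/bin/env Rscript
# Stage 1: synthesise the study.
#
# Emulates the field design (3 trials x 2 tillage treatments x 3
# replicate plots) with planted tillage responses — 3 genes under RT
# at the clayey site, 8 at the loamy site, 1 under CT at the sandy
# site, plus trial-specific family responders — and writes the
# Kaiju-like read-to-family table, the HMMER/DIAMOND-like hit tables,
# the sample metadata and the truth ledger. Depth is scaled to 100,000
# bacterial reads per sample so the whole workflow re-runs in seconds
# (the rarest genes then fall below the support filter, which the
# annotation stage reports); every downstream stage works identically
# at the full ~2.8e6 depth.

suppressMessages(library(epslps))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

design <- study_design(reads_per_sample = 1e5)
truth <- ground_truth(design, seed = seed,
                      effect_ledger = study_effects_ledger(),
                      evalue_range = c(1e-12, 1e-6), p_agree = 1,
                      false_hit_rate = 0)

metadata <- generate_metadata(design, truth)
synth <- generate_read_tables(design, truth)
write_synth(synth, metadata, "results/synth", read_level = "all",
            truth = truth)

cat("samples:", nrow(metadata), " reads/sample:",
    design$reads_per_sample, "\n")
cat("gene-carrying reads planted:", nrow(synth$truth_reads),
    sprintf("(%.4f%% of bacterial reads)\n",
            100 * nrow(synth$truth_reads) / sum(synth$totals)))
cat("written: results/synth/{hits_hmm,hits_blast,read_family,metadata}.tsv",
    "+ truth.json\n")
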