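#!/usr/bin/env Rscript
# Stage 4: robust inference.
#
# Global percentile-bootstrap two-way ANOVA (trial x tillage, median
# M-estimator, 2000 bootstrap resamples) on gene abundances, per-trial
# robust two-group tillage tests, BH FDR within each analysis family,
# and responder classification of families.

suppressMessages(library(epslps))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

read_tab <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  rownames(df) <- df$sample_id
  m <- as.matrix(df[setdiff(names(df),
                            c("sample_id", "total_bacterial_reads"))])
  abundance_table(m, stats::setNames(df$total_bacterial_reads,
                                     df$sample_id))
}
rel_genes <- read_tab("results/rel_abundance_genes.tsv")
abs_genes <- read_tab("results/abs_abundance_genes.tsv")
families <- read_tab("results/rel_abundance_families.tsv")
metadata <- as.data.frame(data.table::fread("results/synth/metadata.tsv"))

set.seed(seed)
seeds <- sample.int(2^31 - 2, 4)
glob_rel <- global_tests(rel_genes, metadata, n_boot = 2000,
                         seed = seeds[1])
glob_abs <- global_tests(abs_genes, metadata, n_boot = 2000,
                         seed = seeds[2])
trial_abs <- tillage_tests_per_trial(abs_genes, metadata, n_boot = 2000,
                                     seed = seeds[3])
trial_fam <- tillage_tests_per_trial(families, metadata, n_boot = 2000,
                                     seed = seeds[4])
responders <- classify_responders(trial_fam, families, alpha = 0.05)

glob <- rbind(cbind(dataset = "rel_genes", glob_rel),
              cbind(dataset = "abs_genes", glob_abs))
data.table::fwrite(glob, "results/tests_global.tsv", sep = "\t")
tri <- rbind(cbind(dataset = "abs_genes", trial_abs),
             cbind(dataset = "families", trial_fam))
data.table::fwrite(tri, "results/tests_per_trial.tsv", sep = "\t")
rec <- responders$records
names(rec)[names(rec) == "log2fc"] <- "log2fc_RT_over_CT"
data.table::fwrite(rec, "results/responders.tsv", sep = "\t")

sig <- function(d) sum(!is.na(d$q) & d$q <= 0.05)
cat("global tests (q <= 0.05): relative genes",
    sig(glob_rel[glob_rel$factor == "tillage", ]), "tillage /",
    sig(glob_rel[glob_rel$factor == "trial", ]), "trial;",
    "absolute genes", sig(glob_abs[glob_abs$factor == "tillage", ]),
    "tillage /", sig(glob_abs[glob_abs$factor == "trial", ]), "trial\n")
for (tr in unique(trial_abs$trial)) {
  n_sig <- sig(trial_abs[trial_abs$trial == tr, ])
  cat(sprintf("%s: %d of %d genes tillage-affected (%.1f%%)\n", tr,
              n_sig, ncol(abs_genes$values),
              100 * n_sig / ncol(abs_genes$values)))
}
cat("responder families per trial:\n")
print(table(responders$records$trial))
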