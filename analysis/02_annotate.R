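#!/usr/bin/env Rscript
# Stage 2: consensus KO annotation.
#
# Parses the hit tables written by stage 1, applies the HMM E-value
# filter (1e-5) plus best-25 aligner unanimity rule, and excludes
# genes with too little read support (fewer than 10 reads or seen in
# fewer than 2 samples).

suppressMessages(library(epslps))

catalog <- load_catalog()
hits <- parse_hit_tables("results/synth/hits_hmm.tsv",
                         "results/synth/hits_blast.tsv",
                         "results/synth/read_family.tsv",
                         catalog = catalog)
assignments <- assign_reads(hits, catalog, e_max = 1e-5, k = 25)
support <- filter_low_support_genes(assignments, catalog = catalog)

data.table::fwrite(assignments, "results/assignments.tsv", sep = "\t")
data.table::fwrite(support$excluded, "results/excluded_genes.tsv",
                   sep = "\t")

withhits <- assignments[assignments$reason != "no-hmm-hit", ]
cat("reads with hit records:", nrow(withhits), "\n")
print(table(withhits$reason))
cat("genes retained:", length(support$retained), "of", nrow(catalog),
    "\n")
if (nrow(support$excluded) > 0) {
  cat("excluded:", paste(support$excluded$gene, collapse = ", "), "\n")
}
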