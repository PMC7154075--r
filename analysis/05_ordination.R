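#!/usr/bin/env Rscript
# Stage 5: ordination and summary report.
#
# PCA of the soil covariates, Bray-Curtis PCoA (Cailliez-corrected)
# of the family profiles and of the family x gene profiles, 95%
# confidence ellipses around the replicate triplets, and the
# cross-trial Venn partition of responder families; everything is
# condensed into results/report.json.

suppressMessages(library(epslps))

read_tab <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  rownames(df) <- df$sample_id
  as.matrix(df[setdiff(names(df),
                       c("sample_id", "total_bacterial_reads"))])
}
families <- read_tab("results/rel_abundance_families.tsv")
profile <- read_tab("results/rel_abundance_family_gene.tsv")
metadata <- as.data.frame(data.table::fread("results/synth/metadata.tsv"))
responders <- as.data.frame(data.table::fread("results/responders.tsv"))
trial_tests <- as.data.frame(data.table::fread("results/tests_per_trial.tsv"))

ord_soil <- pca_soil(metadata)
ord_fam <- pcoa_ord(bray_curtis(families))
keep <- rowSums(profile) > 0
ord_prof <- pcoa_ord(bray_curtis(profile[keep, , drop = FALSE]))

cat("soil PCA: first two axes explain",
    sprintf("%.1f%% + %.1f%%\n", 100 * ord_soil$proportions[1],
            100 * ord_soil$proportions[2]))
cat("family PCoA: Cailliez constant", ord_fam$correction_constant,
    sprintf("; axes 1-2 explain %.1f%% + %.1f%%\n",
            100 * ord_fam$proportions[1], 100 * ord_fam$proportions[2]))

ellipses <- lapply(split(seq_len(nrow(metadata)),
                         paste(metadata$trial, metadata$tillage)),
                   function(ix) {
                     confidence_ellipse(ord_fam$coordinates[
                       metadata$sample_id[ix], 1:2, drop = FALSE])
                   })
n_degen <- sum(vapply(ellipses, `[[`, logical(1), "degenerate"))
cat("ellipses around", length(ellipses), "triplicate groups (",
    n_degen, "degenerate )\n")

sets <- split(responders$family, factor(responders$trial,
                                        levels = unique(metadata$trial)))
venn <- venn_partition(sets)
cat("Venn partition of responder families:\n")
print(venn)

gene_tests <- trial_tests[trial_tests$dataset == "abs_genes", ]
sig_by_trial <- vapply(unique(metadata$trial), function(tr) {
  sum(gene_tests$trial == tr & !is.na(gene_tests$q) &
        gene_tests$q <= 0.05)
}, integer(1))
n_genes <- length(unique(gene_tests$feature))

report <- list(
  n_samples = nrow(metadata),
  n_genes_tested = n_genes,
  sig_genes_abs_per_trial = as.list(sig_by_trial),
  pct_genes_tillage_per_trial =
    as.list(round(100 * sig_by_trial / n_genes, 1)),
  responder_families_per_trial =
    as.list(vapply(sets, length, integer(1))),
  venn = as.list(venn),
  pcoa_family_correction_constant = ord_fam$correction_constant,
  pcoa_profile_correction_constant = ord_prof$correction_constant,
  soil_pca_proportions = round(ord_soil$proportions, 4)
)
jsonlite::write_json(report, "results/report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("written: results/report.json\n")
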