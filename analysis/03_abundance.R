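#!/usr/bin/env Rscript
# Stage 3: abundance estimation.
#
# Relative abundances (percent of total bacterial reads) of genes,
# families and family x gene pairs; Cmic-scaled absolute gene
# abundances; analytic rarefaction curves per sample.

suppressMessages(library(epslps))

catalog <- load_catalog()
assignments <- as.data.frame(data.table::fread("results/assignments.tsv"))
read_family <- as.data.frame(data.table::fread(
  "results/synth/read_family.tsv", na.strings = ""))
metadata <- as.data.frame(data.table::fread("results/synth/metadata.tsv"))
retained <- setdiff(catalog$gene,
                    data.table::fread("results/excluded_genes.tsv")$gene)

# total bacterial reads = all reads in the read-to-family input
totals_tab <- table(read_family$sample_id)
totals <- stats::setNames(as.numeric(totals_tab), names(totals_tab))

asg <- assignments[assignments$reason == "assigned", ]
gene <- catalog$gene[match(asg$ko, catalog$ko)]
counts <- table(factor(asg$sample_id, levels = names(totals)),
                factor(gene, levels = retained))
counts <- matrix(as.integer(counts), length(totals),
                 dimnames = list(names(totals), retained))

rel_genes <- relative_abundance(counts, totals)
abs_genes <- absolute_abundance(rel_genes, metadata)
profile <- family_gene_profile(assignments, read_family, totals, catalog)

rare <- do.call(rbind, lapply(rownames(counts), function(s) {
  if (sum(counts[s, ]) == 0) return(NULL)
  depths <- unique(pmax(1, round(seq(1, sum(counts[s, ]),
                                     length.out = 20))))
  cbind(sample_id = s, rarefaction_curve(counts[s, ], depths))
}))

tab_df <- function(tab) data.frame(sample_id = rownames(tab$values),
                                   tab$values,
                                   total_bacterial_reads = tab$totals,
                                   check.names = FALSE, row.names = NULL)
data.table::fwrite(tab_df(rel_genes), "results/rel_abundance_genes.tsv",
                   sep = "\t")
data.table::fwrite(tab_df(abs_genes), "results/abs_abundance_genes.tsv",
                   sep = "\t")
data.table::fwrite(tab_df(profile$family),
                   "results/rel_abundance_families.tsv", sep = "\t")
data.table::fwrite(tab_df(profile$family_gene),
                   "results/rel_abundance_family_gene.tsv", sep = "\t")
data.table::fwrite(rare, "results/rarefaction.tsv", sep = "\t")

cat(sprintf("assigned gene reads: %d (%.4f%% of bacterial reads)\n",
            sum(counts), 100 * sum(counts) / sum(totals)))
cat("mean relative abundance per gene (%):\n")
print(round(sort(colMeans(rel_genes$values), decreasing = TRUE), 5))
cat("rarefaction: curves for", length(unique(rare$sample_id)),
    "samples written\n")
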