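#' Abundance table container
#'
#' Samples x features matrix of abundances together with the
#' per-sample total bacterial read counts they were normalised by.
#' "Total bacterial reads" means every read classified as bacterial in
#' the read-to-family input, including reads unclassified at family
#' level.
#'
#' @param values Numeric samples x features matrix (rownames = sample
#'   ids, colnames = feature ids).
#' @param totals Named numeric vector of bacterial reads per sample,
#'   aligned with `rownames(values)`.
#' @param unit Unit label, `"percent"` or `"mg/kg"`.
#' @return An object of class `"abundance_table"`.
#' @export
abundance_table <- function(values, totals, unit = "percent") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values needs sample rownames")
  if (!all(rownames(values) %in% names(totals))) {
    stop("totals missing for sample(s): ",
         paste(setdiff(rownames(values), names(totals)), collapse = ", "))
  }
  totals <- totals[rownames(values)]
  if (any(totals <= 0)) {
    stop("degenerate sample(s) with non-positive totals: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  if (any(values < 0)) stop("negative abundance values")
  structure(list(values = values, totals = totals, unit = unit),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Relative abundance as percent of bacterial reads
#'
#' Divides per-feature read counts by the total number of bacterial
#' reads in each sample and multiplies by 100.
#'
#' @param counts Samples x features matrix of read counts (rownames =
#'   sample ids).
#' @param totals Named vector of total bacterial reads per sample; all
#'   must be positive.
#' @return An [abundance_table()] in percent.
#' @export
#' @examples
#' m <- matrix(330, 1, 1, dimnames = list("s1", "wza"))
#' relative_abundance(m, c(s1 = 1e6))$values  # 0.033
relative_abundance <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  tab <- abundance_table(counts, totals, unit = "percent")
  tab$values <- 100 * sweep(counts, 1L, tab$totals, "/")
  tab
}

#' Cmic-scaled absolute abundance
#'
#' Estimates the absolute abundance of each feature by scaling its
#' relative abundance (percent of bacterial reads) with the microbial
#' biomass carbon of the sample:
#' `absolute = relative_percent * Cmic / 100`, in mg biomass-C per kg
#' soil attributed to the feature. This is a biomass-scaled proxy for
#' gene quantity, not a gene copy number.
#'
#' @param rel An [abundance_table()] in percent.
#' @param metadata data.frame with columns `sample_id` and `Cmic`
#'   (mg/kg) covering every sample in `rel`.
#' @return An [abundance_table()] with unit `"mg/kg"`.
#' @export
absolute_abundance <- function(rel, metadata) {
  stopifnot(inherits(rel, "abundance_table"))
  if (rel$unit != "percent") stop("rel must be in percent")
  if (!all(c("sample_id", "Cmic") %in% names(metadata))) {
    stop("metadata needs columns sample_id and Cmic")
  }
  ids <- rownames(rel$values)
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss) > 0L) {
    stop("metadata error: no Cmic for sample(s) ",
         paste(miss, collapse = ", "))
  }
  cmic <- metadata$Cmic[match(ids, metadata$sample_id)]
  if (anyNA(cmic) || any(cmic < 0)) {
    stop("metadata error: missing or negative Cmic")
  }
  out <- rel
  out$values <- sweep(rel$values, 1L, cmic, "*") / 100
  out$unit <- "mg/kg"
  out
}

#' Family x gene profile of assigned reads
#'
#' Cross-tabulates assigned reads by taxonomic family and gene,
#' normalised to percent of total bacterial reads. Reads without a
#' family label (absent from the read-to-family table, or labelled NA)
#' are pooled into an `"unclassified"` bucket, with a warning when
#' assigned reads are missing from the family table. Summing the
#' family x gene shares over families (including unclassified)
#' recovers each gene's total relative abundance.
#'
#' @param assignments Assignment data.frame (see [assign_reads()]);
#'   only rows with `reason == "assigned"` are counted.
#' @param read_family data.frame with `read_id`, `sample_id`,
#'   `family`.
#' @param totals Named vector of total bacterial reads per sample.
#' @param catalog Catalog mapping `ko` to `gene` names.
#' @return List with [abundance_table()]s `family_gene` (features
#'   `"family|gene"`), `gene` (per-gene marginal), and
#'   `family` (per-family totals of gene-assigned reads).
#' @export
family_gene_profile <- function(assignments, read_family, totals,
                                catalog = eps_lps_catalog()) {
  asg <- assignments[assignments$reason == "assigned", , drop = FALSE]
  samples <- names(totals)
  gene <- catalog$gene[match(asg$ko, catalog$ko)]
  key <- paste(asg$read_id, asg$sample_id, sep = "\r")
  fkey <- paste(read_family$read_id, read_family$sample_id, sep = "\r")
  fam <- read_family$family[match(key, fkey)]
  n_missing <- sum(is.na(fam) & !(key %in% fkey))
  if (n_missing > 0L) {
    warning(n_missing, " assigned read(s) absent from the family table;",
            " counted as unclassified")
  }
  fam[is.na(fam) | !nzchar(fam)] <- "unclassified"
  fg <- paste(fam, gene, sep = "|")
  counts_fg <- .cross_counts(asg$sample_id, fg, samples)
  counts_g <- .cross_counts(asg$sample_id, gene, samples)
  counts_f <- .cross_counts(asg$sample_id, fam, samples)
  list(
    family_gene = relative_abundance(counts_fg, totals),
    gene = relative_abundance(counts_g, totals),
    family = relative_abundance(counts_f, totals)
  )
}

# samples x feature count matrix including empty samples
.cross_counts <- function(sample_id, feature, samples) {
  tab <- table(factor(sample_id, levels = samples), feature)
  m <- matrix(as.integer(tab), nrow = length(samples),
              dimnames = list(samples, colnames(tab)))
  m
}

#' Analytic rarefaction curve
#'
#' Expected number of distinct genes observed in a random subsample of
#' n reads drawn without replacement from a sample's gene reads,
#' \deqn{E[S_n] = \sum_g 1 - \binom{N - N_g}{n} / \binom{N}{n}}
#' computed exactly (hypergeometric form, via [vegan::rarefy()]).
#'
#' @param counts Named integer vector of reads per gene for one
#'   sample.
#' @param depths Integer subsampling depths, each <= `sum(counts)`.
#' @return data.frame with columns `depth` and `expected_genes`;
#'   non-decreasing in depth, equal to the observed richness at full
#'   depth.
#' @export
#' @examples
#' rarefaction_curve(c(A = 3, B = 1), depths = c(1, 2, 4))
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no gene reads")
  if (any(counts != round(counts))) stop("counts must be integers")
  n_tot <- sum(counts)
  depths <- as.integer(depths)
  if (any(depths < 1L) || any(depths > n_tot)) {
    stop("depths must lie in [1, ", n_tot, "]")
  }
  # rarefy warns about datasets without singletons; the expectation
  # formula is exact regardless
  exp_rich <- as.numeric(suppressWarnings(
    vegan::rarefy(matrix(counts, nrow = 1L), sample = depths)))
  data.frame(depth = depths, expected_genes = exp_rich)
}
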