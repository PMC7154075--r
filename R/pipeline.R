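#' Planted effects emulating a site-specific tillage response pattern
#'
#' An effect ledger for the emulated field study's response structure: 3
#' genes boosted under reduced tillage at the clayey site, 8 at the
#' loamy site, 1 favoured under conventional tillage at the sandy
#' site, plus a set of family-level responders with trial-dependent
#' (and for some families opposite) directions.
#'
#' @param gene_effect Multiplicative effect on boosted genes
#'   (default 2.5).
#' @param family_effect Multiplicative effect on responder families
#'   (default 3).
#' @return data.frame usable as `effect_ledger` in [ground_truth()].
#' @export
study_effects_ledger <- function(gene_effect = 2.5, family_effect = 3) {
  g <- function(genes, trial, tillage) {
    data.frame(feature = genes, type = "gene", trial = trial,
               tillage = tillage, effect = gene_effect,
               stringsAsFactors = FALSE)
  }
  f <- function(fams, trial, tillage) {
    data.frame(feature = fams, type = "family", trial = trial,
               tillage = tillage, effect = family_effect,
               stringsAsFactors = FALSE)
  }
  rbind(
    g(c("wza", "kpsE", "wzt"), "Frick", "RT"),
    g(c("wza", "wcaB", "wcaF", "algJ", "sacB", "wzt", "lptF", "lptG"),
      "Moskanjci", "RT"),
    g("sacB", "Juchowo", "CT"),
    f(c("Acetobacteraceae", "Geodermatophilaceae", "Cellulomonadaceae"),
      "Frick", "RT"),
    f(c("Flavobacteriaceae", "Cytophagaceae"), "Frick", "CT"),
    f(c("Cytophagaceae", "Mycobacteriaceae"), "Moskanjci", "RT"),
    f("Oxalobacteraceae", "Moskanjci", "CT"),
    f(c("Acetobacteraceae", "Flavobacteriaceae", "Oxalobacteraceae",
        "Nocardioidaceae"), "Juchowo", "RT")
  )
}

#' Pipeline configuration
#'
#' Bundles the design, ground truth and analysis parameters of one
#' pipeline run. With `detection = "calibrated"` the generator
#' emulates already-thresholded hit tables (all HMM E-values below
#' the cutoff, unanimous aligner hits, no spurious hits), so the
#' assigned gene fraction matches the planted fraction; the
#' `"default"` detection draws E-values straddling the 1e-5 cutoff
#' and lets 10% of gene reads fail the aligner consensus.
#'
#' @param design A [study_design()].
#' @param seed Master seed for the whole run.
#' @param effects Optional effect ledger (see [ground_truth()]).
#' @param detection `"default"` or `"calibrated"`.
#' @param e_max,k Annotation thresholds (HMM E-value cutoff, top-k
#'   aligner hits).
#' @param min_reads,min_samples Low-support gene exclusion limits.
#' @param n_boot Bootstrap resamples for all robust tests.
#' @param alpha Significance level on BH-adjusted q-values.
#' @param ... Further arguments passed to [ground_truth()].
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(design = study_design(), seed = 1L,
                            effects = NULL,
                            detection = c("default", "calibrated"),
                            e_max = 1e-5, k = 25, min_reads = 10,
                            min_samples = 2, n_boot = 2000,
                            alpha = 0.05, ...) {
  detection <- match.arg(detection)
  extra <- list(...)
  if (detection == "calibrated") {
    extra$evalue_range <- c(1e-12, 1e-6)
    extra$p_agree <- 1
    extra$false_hit_rate <- 0
  }
  truth <- do.call(ground_truth,
                   c(list(design = design, seed = seed,
                          effect_ledger = effects), extra))
  structure(list(design = design, truth = truth, seed = as.integer(seed),
                 detection = detection, e_max = e_max, k = k,
                 min_reads = min_reads, min_samples = min_samples,
                 n_boot = n_boot, alpha = alpha),
            class = "pipeline_config")
}

# samples x genes count matrix from assignments
.gene_counts <- function(assignments, catalog, samples) {
  asg <- assignments[assignments$reason == "assigned", , drop = FALSE]
  gene <- catalog$gene[match(asg$ko, catalog$ko)]
  tab <- table(factor(asg$sample_id, levels = samples),
               factor(gene, levels = catalog$gene))
  matrix(as.integer(tab), length(samples),
         dimnames = list(samples, catalog$gene))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage in order: synthesis (metadata + read tables),
#' consensus KO annotation, low-support gene exclusion, relative and
#' Cmic-scaled absolute abundance estimation, family x gene
#' profiling, rarefaction, global robust two-way tests (trial x
#' tillage) and per-trial robust two-group tillage tests with BH
#' adjustment, ordination (PCA of soil covariates, Bray-Curtis PCoA
#' of family and family-gene profiles with Cailliez correction), and
#' responder classification with the cross-trial Venn partition. The
#' run is fully reproducible from the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, all tables are
#'   written as TSV and the summary as `report.json`.
#' @return List of class `"epslps_pipeline"` with the per-stage
#'   results and a `report` summary list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design; truth <- config$truth
  catalog <- eps_lps_catalog()
  if (design$replicates < 5L) {
    warning("group size ", design$replicates,
            " < 5: percentile-bootstrap granularity is coarse",
            call. = FALSE)
  }

  metadata <- generate_metadata(design, truth)
  synth <- generate_read_tables(design, truth, catalog)

  hits <- structure(list(hmm = synth$hits_hmm, blast = synth$hits_blast,
                         reads = synth$read_family), class = "read_hits")
  assignments <- assign_reads(hits, catalog, e_max = config$e_max,
                              k = config$k)
  support <- filter_low_support_genes(assignments,
                                      min_reads = config$min_reads,
                                      min_samples = config$min_samples,
                                      catalog = catalog)

  totals <- synth$totals
  counts <- .gene_counts(assignments, catalog, names(totals))
  counts_kept <- counts[, support$retained, drop = FALSE]
  rel_genes <- relative_abundance(counts_kept, totals)
  abs_genes <- absolute_abundance(rel_genes, metadata)

  fam_counts <- synth$family_counts
  fam_cols <- setdiff(colnames(fam_counts), "unclassified")
  rel_families <- relative_abundance(fam_counts[, fam_cols, drop = FALSE],
                                     totals)
  profile <- suppressWarnings(
    family_gene_profile(assignments, synth$read_family, totals, catalog))

  rare <- lapply(rownames(counts), function(s) {
    cs <- counts[s, ]
    if (sum(cs) == 0L) return(NULL)
    depths <- unique(pmax(1L, round(seq(1L, sum(cs), length.out = 20L))))
    cbind(sample_id = s, rarefaction_curve(cs, depths))
  })
  rare <- do.call(rbind, rare)

  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 6L)
  # the two-way tests need both factors; a single-trial run keeps only
  # the per-trial two-group analyses
  two_way_defined <- length(design$trials) >= 2L &&
    length(design$tillage) >= 2L
  glob_rel <- glob_abs <- glob_fam <- NULL
  if (two_way_defined) {
    glob_rel <- global_tests(rel_genes, metadata, n_boot = config$n_boot,
                             seed = seeds[1L])
    glob_abs <- global_tests(abs_genes, metadata, n_boot = config$n_boot,
                             seed = seeds[2L])
    glob_fam <- global_tests(rel_families, metadata, n_boot = config$n_boot,
                             seed = seeds[3L])
  }
  trial_rel <- tillage_tests_per_trial(rel_genes, metadata,
                                       ct = design$tillage[1L],
                                       rt = design$tillage[2L],
                                       n_boot = config$n_boot,
                                       seed = seeds[4L])
  trial_abs <- tillage_tests_per_trial(abs_genes, metadata,
                                       ct = design$tillage[1L],
                                       rt = design$tillage[2L],
                                       n_boot = config$n_boot,
                                       seed = seeds[5L])
  trial_fam <- tillage_tests_per_trial(profile$family, metadata,
                                       ct = design$tillage[1L],
                                       rt = design$tillage[2L],
                                       n_boot = config$n_boot,
                                       seed = seeds[6L])
  responders <- classify_responders(trial_fam, profile$family,
                                    alpha = config$alpha)

  ord_soil <- pca_soil(metadata)
  ord_fam <- pcoa_ord(bray_curtis(rel_families))
  # samples without any assigned gene read have no defined Bray-Curtis
  # profile; they are left out of the gene-profile ordination
  pg <- profile$family_gene$values
  has_genes <- rowSums(pg) > 0
  ord_prof <- if (sum(has_genes) >= 2L) {
    pcoa_ord(bray_curtis(pg[has_genes, , drop = FALSE]))
  } else NULL

  n_retained <- length(support$retained)
  sig_per_trial <- function(tt) {
    vapply(design$trials, function(tr) {
      sum(tt$trial == tr & !is.na(tt$q) & tt$q <= config$alpha)
    }, integer(1))
  }
  sig_rel <- sig_per_trial(trial_rel)
  sig_abs <- sig_per_trial(trial_abs)
  fams_detected <- colnames(fam_counts)[colSums(fam_counts) > 0]
  fams_detected <- setdiff(fams_detected, "unclassified")
  fam_gene_cols <- colnames(profile$family$values)
  fams_with_genes <- setdiff(fam_gene_cols[colSums(profile$family$values) > 0],
                             "unclassified")
  fams_with_genes <- intersect(fams_with_genes, fams_detected)
  resp_counts <- vapply(design$trials, function(tr) {
    sum(responders$records$trial == tr)
  }, integer(1))

  gene_reads_total <- sum(counts)
  report <- list(
    seed = config$seed,
    detection = config$detection,
    n_samples = nrow(metadata),
    reads_per_sample = design$reads_per_sample,
    gene_reads_assigned = gene_reads_total,
    gene_fraction_pct = 100 * gene_reads_total / sum(totals),
    retained_genes = support$retained,
    excluded_genes = support$excluded$gene,
    n_families_detected = length(fams_detected),
    n_families_with_genes = length(fams_with_genes),
    pct_families_with_genes =
      100 * length(fams_with_genes) / length(fams_detected),
    sig_genes_rel_per_trial = as.list(sig_rel),
    sig_genes_abs_per_trial = as.list(sig_abs),
    pct_genes_tillage_per_trial =
      as.list(round(100 * sig_rel / n_retained, 1)),
    responder_families_per_trial = as.list(resp_counts),
    venn = as.list(responders$venn),
    pcoa_family_correction_constant = ord_fam$correction_constant
  )

  out <- structure(list(
    config = config, metadata = metadata, synth = synth,
    assignments = assignments, support = support,
    rel_genes = rel_genes, abs_genes = abs_genes,
    rel_families = rel_families, profile = profile,
    rarefaction = rare,
    global_tests = list(rel_genes = glob_rel, abs_genes = glob_abs,
                        families = glob_fam),
    trial_tests = list(rel_genes = trial_rel, abs_genes = trial_abs,
                       families = trial_fam),
    responders = responders,
    ordinations = list(soil = ord_soil, families = ord_fam,
                       family_gene = ord_prof),
    report = report
  ), class = "epslps_pipeline")

  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

#' Write pipeline outputs to a directory
#'
#' Writes the abundance tables, test tables, responder records and
#' `report.json` (byte-identical across runs with the same
#' configuration and seed).
#'
#' @param result An `"epslps_pipeline"` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    data.table::fwrite(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       na = "")
  }
  tab_df <- function(tab) {
    data.frame(sample_id = rownames(tab$values), tab$values,
               total_bacterial_reads = tab$totals,
               check.names = FALSE, row.names = NULL)
  }
  wr(result$metadata, "metadata.tsv")
  wr(result$assignments, "assignments.tsv")
  wr(result$support$excluded, "excluded_genes.tsv")
  wr(tab_df(result$rel_genes), "rel_abundance_genes.tsv")
  wr(tab_df(result$abs_genes), "abs_abundance_genes.tsv")
  wr(tab_df(result$rel_families), "rel_abundance_families.tsv")
  wr(tab_df(result$profile$family_gene), "rel_abundance_family_gene.tsv")
  wr(result$rarefaction, "rarefaction.tsv")
  gt <- Filter(Negate(is.null), result$global_tests)
  if (length(gt) > 0L) {
    glob <- do.call(rbind, Map(function(d, nm) cbind(dataset = nm, d),
                               gt, names(gt)))
    wr(glob, "tests_global.tsv")
  }
  tri <- do.call(rbind, Map(function(d, nm) cbind(dataset = nm, d),
                            result$trial_tests, names(result$trial_tests)))
  wr(tri, "tests_per_trial.tsv")
  # log2fc column header records the RT/CT orientation
  rec <- result$responders$records
  names(rec)[names(rec) == "log2fc"] <- "log2fc_RT_over_CT"
  wr(rec, "responders.tsv")
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.epslps_pipeline <- function(x, ...) {
  r <- x$report
  cat("EPS/LPS profiling pipeline run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  %d samples x %s reads; %d gene reads assigned (%.4f%% of bacterial reads)\n",
              r$n_samples, format(r$reads_per_sample, big.mark = ","),
              r$gene_reads_assigned, r$gene_fraction_pct))
  cat(sprintf("  genes retained: %d of %d; families carrying genes: %d/%d (%.1f%%)\n",
              length(r$retained_genes),
              length(r$retained_genes) + length(r$excluded_genes),
              r$n_families_with_genes, r$n_families_detected,
              r$pct_families_with_genes))
  cat("  tillage-affected genes per trial (%):",
      paste(sprintf("%s %.1f", names(r$pct_genes_tillage_per_trial),
                    unlist(r$pct_genes_tillage_per_trial)),
            collapse = ", "), "\n")
  cat("  responder families per trial:",
      paste(sprintf("%s %d", names(r$responder_families_per_trial),
                    unlist(r$responder_families_per_trial)),
            collapse = ", "), "\n")
  invisible(x)
}
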