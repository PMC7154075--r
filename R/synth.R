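## Synthetic study generator: emulates the hit tables (HMMER-tblout-like,
## DIAMOND-outfmt6-like), the Kaiju-like read-to-family map and the
## sample metadata of a 3-trial x 2-tillage x 3-replicate soil
## metagenome study, with known planted site and tillage effects.

#' Study design
#'
#' The factorial layout of the emulated field study: trials (sites) x
#' tillage treatments x replicate plots, with a fixed number of
#' bacterial reads per sample.
#'
#' @param trials Character vector of trial (site) labels.
#' @param tillage Character vector of tillage levels (default CT =
#'   conventional, RT = reduced).
#' @param replicates Replicate plots per trial x tillage cell.
#' @param reads_per_sample Bacterial reads per sample; the default
#'   matches the depth of a typical shotgun soil metagenome
#'   (~2.8 million filtered reads).
#' @return A list of class `"study_design"`.
#' @export
study_design <- function(trials = c("Frick", "Moskanjci", "Juchowo"),
                         tillage = c("CT", "RT"),
                         replicates = 3L,
                         reads_per_sample = 2.8e6) {
  if (length(trials) < 1L || anyDuplicated(trials)) {
    stop("trials must be a non-empty set of unique labels")
  }
  if (length(tillage) < 1L || anyDuplicated(tillage)) {
    stop("tillage must be a non-empty set of unique labels")
  }
  if (replicates < 1L) stop("replicates_per_cell must be >= 1")
  if (reads_per_sample < 1) stop("reads_per_sample must be >= 1")
  structure(list(trials = trials, tillage = tillage,
                 replicates = as.integer(replicates),
                 reads_per_sample = as.integer(reads_per_sample)),
            class = "study_design")
}

#' Sample sheet of a design
#' @param design A [study_design()].
#' @return data.frame with `sample_id`, `trial`, `tillage`,
#'   `replicate`, one row per sample.
#' @export
design_samples <- function(design) {
  g <- expand.grid(replicate = seq_len(design$replicates),
                   tillage = design$tillage, trial = design$trials,
                   stringsAsFactors = FALSE)
  g <- g[, c("trial", "tillage", "replicate")]
  g$sample_id <- sprintf("%s_%s_R%d", g$trial, g$tillage, g$replicate)
  g[c("sample_id", "trial", "tillage", "replicate")]
}

# printed site means of the soil covariates (units: %, mg/kg, pH)
.default_site_means <- function() {
  data.frame(
    trial = c("Frick", "Moskanjci", "Juchowo"),
    clay = c(46.5, 17.6, 2.4), silt = c(24.5, 43.4, 6.4),
    sand = c(29.0, 39.0, 91.2), SAF = c(94.3, 69.3, 5.5),
    Corg = c(2.66, 1.59, 0.81), DOC = c(68.8, 22.5, 42.2),
    DON = c(12.0, 3.1, 10.8), pH = c(7.2, 6.7, 6.3),
    Cmic = c(1341.9, 342.2, 121.5), Nmic = c(191.3, 53.0, 18.5),
    stringsAsFactors = FALSE
  )
}

# relative tillage offsets: value in cell = site mean * (1 +/- delta),
# + under RT, - under CT, so the trial mean stays at the site mean.
# Cmic/Nmic/Corg respond to reduced tillage everywhere; SAF and pH only
# at the loamy site (trial x tillage interaction).
.default_tillage_deltas <- function() {
  data.frame(
    variable = c("Cmic", "Nmic", "Corg", "SAF", "pH"),
    trial = c(NA, NA, NA, "Moskanjci", "Moskanjci"),
    delta = c(0.10, 0.10, 0.05, 0.08, 0.03),
    stringsAsFactors = FALSE
  )
}

# 14 dominant families named in soil shotgun surveys of these systems
.dominant_families <- function() {
  c(Bradyrhizobiaceae = 0.046, Streptomycetaceae = 0.031,
    Sphingomonadaceae = 0.022, Mycobacteriaceae = 0.018,
    Nocardioidaceae = 0.016, Micromonosporaceae = 0.014,
    Flavobacteriaceae = 0.013, Acetobacteraceae = 0.012,
    Cytophagaceae = 0.012, Oxalobacteraceae = 0.012,
    Glycomycetaceae = 0.011, Dermatophilaceae = 0.011,
    Geodermatophilaceae = 0.011, Cellulomonadaceae = 0.011)
}

# per-gene read fractions: three tiers matching the observed abundance
# structure (dominant ~0.0075%, moderate ~0.0015%, rare <0.001% of
# bacterial reads); weights are rescaled to the planted total fraction
.default_gene_weights <- function() {
  c(wza = 15, wcaB = 3, wcaF = 3, `wcaK/amsJ` = 1.4, kpsE = 3,
    algE = 1.4, algJ = 1, sacB = 1, wzt = 3, lptC = 3,
    lptF = 15, lptG = 15)
}

#' Ground truth of a synthetic study
#'
#' Fixes everything the generator needs: the fraction of bacterial
#' reads carrying catalog genes (default 0.033%), the per-gene read
#' fractions, per-trial family compositions (Dirichlet draws around a
#' dominant-family profile, with 35.8% of bacterial reads left
#' unclassified at family level), the planted effect ledger, the soil
#' covariate model, and the detection model for the emulated hit
#' tables (HMM E-value range, aligner agreement probability, false-hit
#' rate).
#'
#' @param design A [study_design()].
#' @param seed Integer master seed; every stream of randomness in the
#'   generator derives from it.
#' @param planted_gene_fraction Proportion of bacterial reads carrying
#'   a catalog gene (default 3.3e-4 = 0.033%).
#' @param gene_weights Named positive weights over catalog genes,
#'   rescaled to sum to `planted_gene_fraction`.
#' @param effect_ledger data.frame with columns `feature`, `type`
#'   (`"gene"` or `"family"`), `trial`, `tillage`, `effect` (> 0): the
#'   planted gene-read rate ratio of the named tillage level over the
#'   other level for that feature in that trial. Both cells are
#'   rescaled so that the mean rate over the tillage pair stays at
#'   baseline, keeping the overall planted gene fraction unchanged.
#' @param n_tail_families Number of low-abundance tail families added
#'   to the 14 named dominant families. The default 371 gives a
#'   385-family inventory; tail shares decay geometrically from just
#'   below the 1% dominance threshold down to the ultra-rare range
#'   (the six rarest families together hold ~0.0002% of bacterial
#'   reads), emulating the long rank-abundance tail of soil
#'   metagenomes.
#' @param unclassified_fraction Fraction of bacterial reads not
#'   classified at family level (default 0.358).
#' @param dirichlet_conc Concentration of the per-trial Dirichlet draw
#'   around the family baseline (larger = sites more alike).
#' @param cmic_model List with `site_means` (data.frame of per-trial
#'   covariate means), `tillage_deltas`, and `noise_cv` (relative
#'   Gaussian noise; pH uses an absolute sd of the same magnitude).
#' @param evalue_range HMM E-values are drawn log-uniformly over this
#'   range; the default straddles the 1e-5 cutoff so the threshold is
#'   exercised on both sides.
#' @param p_agree Probability that the 25 aligner hits of a gene read
#'   unanimously agree with its true KO.
#' @param unlabeled_rate Probability that an aligner hit lacks a KO
#'   label.
#' @param false_hit_rate Probability that a decoy (non-gene) read
#'   receives a spurious hit record.
#' @return List of class `"ground_truth"`.
#' @export
ground_truth <- function(design = study_design(), seed = 1L,
                         planted_gene_fraction = 3.3e-4,
                         gene_weights = .default_gene_weights(),
                         effect_ledger = NULL,
                         n_tail_families = 371L,
                         unclassified_fraction = 0.358,
                         dirichlet_conc = 2000,
                         cmic_model = NULL,
                         evalue_range = c(1e-12, 1e-2),
                         p_agree = 0.9,
                         unlabeled_rate = 0.04,
                         false_hit_rate = 1e-5) {
  stopifnot(inherits(design, "study_design"))
  if (planted_gene_fraction < 0 || planted_gene_fraction >= 1) {
    stop("planted_gene_fraction must lie in [0, 1)")
  }
  if (p_agree < 0 || p_agree > 1) stop("p_agree must lie in [0, 1]")
  if (any(gene_weights <= 0)) stop("gene_weights must be positive")
  if (is.null(cmic_model)) {
    cmic_model <- list(site_means = .default_site_means(),
                       tillage_deltas = .default_tillage_deltas(),
                       noise_cv = 0.05)
  }
  sm <- cmic_model$site_means
  # recycle covariate rows for trials absent from the site table
  idx <- match(design$trials, sm$trial)
  idx[is.na(idx)] <- rep_len(seq_len(nrow(sm)), sum(is.na(idx)))
  sm <- sm[idx, , drop = FALSE]
  sm$trial <- design$trials
  cmic_model$site_means <- sm
  if (any(sm$Cmic <= 0)) stop("invalid parameter: non-positive Cmic mean")

  if (is.null(effect_ledger)) {
    effect_ledger <- data.frame(feature = character(), type = character(),
                                trial = character(), tillage = character(),
                                effect = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(effect_ledger) > 0L && any(effect_ledger$effect <= 0)) {
    stop("multiplicative effects must be > 0")
  }

  gene_rates <- planted_gene_fraction * gene_weights / sum(gene_weights)

  fam_base <- .dominant_families()
  if (n_tail_families > 0L) {
    tail_total <- 1 - unclassified_fraction - sum(fam_base)
    if (tail_total < 0) stop("family baseline exceeds classified fraction")
    # geometric rank-abundance decay from just below the 1% dominance
    # threshold to the ultra-rare range, rescaled to the tail mass
    tail <- 10^seq(log10(9e-3), log10(3.3e-7),
                   length.out = n_tail_families)
    tail <- tail * (tail_total / sum(tail))
    names(tail) <- sprintf("Family%03d", seq_len(n_tail_families))
    fam_base <- c(fam_base, tail)
  }
  fam_base <- c(fam_base, unclassified = unclassified_fraction)
  fam_base <- fam_base / sum(fam_base)

  set.seed(seed)
  # per-trial composition: Dirichlet over the dominant families, the
  # aggregate tail mass and the unclassified fraction; the within-tail
  # shares keep their fixed geometric profile (a per-family Dirichlet
  # with realistic concentrations would extinguish rare families,
  # whereas nearly all families occur at every site)
  dom <- .dominant_families()
  tail_names <- setdiff(names(fam_base), c(names(dom), "unclassified"))
  blocks <- c(fam_base[names(dom)],
              tail = sum(fam_base[tail_names]),
              unclassified = unname(fam_base["unclassified"]))
  comp <- t(vapply(design$trials, function(tr) {
    g <- stats::rgamma(length(blocks), shape = blocks * dirichlet_conc)
    b <- stats::setNames(g / sum(g), names(blocks))
    tail_shares <- if (length(tail_names) > 0L) {
      b[["tail"]] * fam_base[tail_names] / sum(fam_base[tail_names])
    } else numeric(0)
    c(b[names(dom)], tail_shares, unclassified = b[["unclassified"]])
  }, numeric(length(fam_base))))
  colnames(comp) <- names(fam_base)
  rownames(comp) <- design$trials
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)

  structure(list(
    seed = as.integer(seed),
    planted_gene_fraction = planted_gene_fraction,
    gene_rates = gene_rates,
    family_baselines = comp,
    effect_ledger = effect_ledger,
    cmic_model = cmic_model,
    evalue_range = evalue_range,
    p_agree = p_agree,
    unlabeled_rate = unlabeled_rate,
    false_hit_rate = false_hit_rate,
    stream_seeds = list(metadata = sub_seeds[1L], reads = sub_seeds[2L])
  ), class = "ground_truth")
}

#' Generate sample metadata
#'
#' One row per sample with the design factors and the soil
#' physicochemical and microbial-biomass covariates (clay, silt, sand,
#' SAF, Corg, DOC, DON, pH, Cmic, Nmic, Cmic/Nmic), drawn from the
#' per-cell means of the covariate model plus relative Gaussian noise.
#' With `noise_cv = 0` the per-trial means equal the model site means
#' exactly.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth()].
#' @return data.frame of sample metadata.
#' @export
generate_metadata <- function(design, truth) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))
  cm <- truth$cmic_model
  sm <- cm$site_means
  if (any(sm$Cmic <= 0)) stop("invalid parameter: non-positive Cmic mean")
  deltas <- cm$tillage_deltas
  cv <- cm$noise_cv
  samp <- design_samples(design)
  vars <- setdiff(names(sm), "trial")
  set.seed(truth$stream_seeds$metadata)
  # tillage direction: +1 for the last (reduced) level, -1 for the first
  dir_of <- function(till) {
    ifelse(till == design$tillage[length(design$tillage)], 1,
           ifelse(till == design$tillage[1L], -1, 0))
  }
  for (v in vars) {
    mu <- sm[[v]][match(samp$trial, sm$trial)]
    d <- deltas[deltas$variable == v, , drop = FALSE]
    if (nrow(d) > 0L) {
      for (i in seq_len(nrow(d))) {
        sel <- if (is.na(d$trial[i])) rep(TRUE, nrow(samp)) else
          samp$trial == d$trial[i]
        mu[sel] <- mu[sel] * (1 + dir_of(samp$tillage[sel]) * d$delta[i])
      }
    }
    noise <- if (v == "pH") stats::rnorm(nrow(samp), 0, cv) else
      mu * stats::rnorm(nrow(samp), 0, cv)
    samp[[v]] <- mu + noise
  }
  if (any(samp$Cmic <= 0) || any(samp$Nmic <= 0)) {
    stop("noise drew non-positive Cmic/Nmic; lower noise_cv")
  }
  samp$Cmic_Nmic <- samp$Cmic / samp$Nmic
  samp
}

# rate matrix of gene-carrying reads for one trial x tillage cell:
# genes x families (incl. unclassified), entries = expected fraction of
# bacterial reads
.cell_rates <- function(truth, catalog, trial, tillage) {
  rates <- truth$gene_rates[catalog$gene]
  if (anyNA(rates)) {
    stop("truth has no gene rate for: ",
         paste(catalog$gene[is.na(rates)], collapse = ", "))
  }
  shares <- truth$family_baselines[trial, ]
  m <- outer(rates, shares)
  led <- truth$effect_ledger
  if (nrow(led) > 0L) {
    for (i in seq_len(nrow(led))) {
      if (led$trial[i] != trial) next
      # the effect is the planted rate ratio between the named tillage
      # level and the other level; both cells are rescaled so that the
      # mean rate over the tillage pair stays at baseline
      e <- led$effect[i]
      f <- if (led$tillage[i] == tillage) 2 * e / (1 + e) else 2 / (1 + e)
      if (led$type[i] == "gene") {
        j <- match(led$feature[i], catalog$gene)
        if (!is.na(j)) m[j, ] <- m[j, ] * f
      } else {
        j <- match(led$feature[i], colnames(truth$family_baselines))
        if (!is.na(j)) m[, j] <- m[, j] * f
      }
    }
  }
  m
}

#' Generate read-level hit tables with a truth ledger
#'
#' For every sample, draws the exact multinomial split of
#' `reads_per_sample` bacterial reads over (gene x family) cells and
#' decoys, then materialises hit records for the gene-carrying reads:
#' one profile-HMM hit (E-value log-uniform over
#' `truth$evalue_range`) and a ranked list of 25 aligner hits that
#' unanimously carry the true KO with probability `truth$p_agree` and
#' otherwise contain at least one discordant catalog KO. Decoy reads
#' receive spurious hit records at `truth$false_hit_rate` (random HMM,
#' mixed aligner KOs). Per sample, gene reads + decoy reads equal
#' `reads_per_sample` exactly.
#'
#' Read-level rows are only materialised for reads appearing in the
#' hit tables; the family composition of all reads is carried as an
#' exact count matrix (`family_counts`). Use [write_synth()] with
#' `read_level = "all"` to materialise the full Kaiju-like
#' read-to-family table.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth()].
#' @param catalog Gene catalog.
#' @return List of class `"synth_reads"`: `hits_hmm`, `hits_blast`,
#'   `read_family` (reads occurring in the hit tables), `family_counts`
#'   (samples x families count matrix incl. `unclassified`), `totals`
#'   (bacterial reads per sample), `truth_reads` (ledger of every
#'   gene-carrying read: read_id, sample_id, gene, family), and
#'   `samples`.
#' @export
generate_read_tables <- function(design, truth, catalog = eps_lps_catalog()) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))
  if (nrow(catalog) == 0L) stop("catalog is empty")
  samp <- design_samples(design)
  fams <- colnames(truth$family_baselines)
  n_fam <- length(fams)
  hmm_ids <- strsplit(catalog$hmm_ids, ",", fixed = TRUE)
  kos <- catalog$ko
  lo <- log10(truth$evalue_range[1L]); hi <- log10(truth$evalue_range[2L])

  set.seed(truth$stream_seeds$reads)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, nrow(samp))

  hmm_l <- list(); blast_l <- list(); fam_l <- list(); truth_l <- list()
  fam_counts <- matrix(0L, nrow(samp), n_fam,
                       dimnames = list(samp$sample_id, fams))
  n_reads <- design$reads_per_sample

  for (s in seq_len(nrow(samp))) {
    set.seed(sample_seeds[s])
    sid <- samp$sample_id[s]
    rates <- .cell_rates(truth, catalog, samp$trial[s], samp$tillage[s])
    p <- as.vector(rates)  # genes fastest (column-major over genes x fams)
    if (sum(p) >= 1) stop("gene rates exceed 1; check effect ledger")
    counts <- as.integer(stats::rmultinom(1L, n_reads, c(p, 1 - sum(p))))
    cell_counts <- matrix(counts[-length(counts)], nrow(catalog), n_fam)
    n_gene <- sum(cell_counts)
    n_decoy <- n_reads - n_gene

    # families of the decoy reads
    shares <- truth$family_baselines[samp$trial[s], ]
    decoy_fam <- as.integer(stats::rmultinom(1L, n_decoy, shares))
    fam_counts[s, ] <- decoy_fam + colSums(cell_counts)

    if (n_gene > 0L) {
      gi <- rep(rep(seq_len(nrow(catalog)), n_fam), as.vector(cell_counts))
      fi <- rep(rep(seq_len(n_fam), each = nrow(catalog)),
                as.vector(cell_counts))
      rid <- sprintf("%s_r%07d", sid, seq_len(n_gene))
      truth_l[[s]] <- data.frame(read_id = rid, sample_id = sid,
                                 gene = catalog$gene[gi], family = fams[fi],
                                 stringsAsFactors = FALSE)
      # one HMM hit per gene read
      hid <- vapply(gi, function(g) {
        ids <- hmm_ids[[g]]
        if (length(ids) == 1L) ids else ids[sample.int(length(ids), 1L)]
      }, character(1))
      ev <- 10^stats::runif(n_gene, lo, hi)
      hmm_l[[s]] <- data.frame(read_id = rid, sample_id = sid,
                               hmm_id = hid, evalue = ev,
                               stringsAsFactors = FALSE)
      # 25 ranked aligner hits per gene read
      bs <- apply(matrix(stats::runif(25L * n_gene, 60, 300), 25L),
                  2L, sort, decreasing = TRUE)
      ko_mat <- matrix(rep(kos[gi], each = 25L), 25L)
      discord <- stats::runif(n_gene) > truth$p_agree
      for (j in which(discord)) {
        n_bad <- 1L + stats::rbinom(1L, 2L, 0.5)
        pos <- sample.int(25L, n_bad)
        ko_mat[pos, j] <- sample(setdiff(kos, kos[gi[j]]), n_bad,
                                 replace = TRUE)
      }
      unlab <- matrix(stats::runif(25L * n_gene) < truth$unlabeled_rate, 25L)
      # keep at least one labelled hit per read
      all_unlab <- which(colSums(!unlab) == 0L)
      if (length(all_unlab) > 0L) unlab[1L, all_unlab] <- FALSE
      ko_vec <- as.vector(ko_mat)
      ko_vec[as.vector(unlab)] <- NA_character_
      blast_l[[s]] <- data.frame(
        read_id = rep(rid, each = 25L), sample_id = sid,
        rank = rep(1:25, n_gene), subject_ko = ko_vec,
        bit_score = round(as.vector(bs), 1),
        stringsAsFactors = FALSE)
    }

    # spurious hit records on decoy reads
    n_false <- if (truth$false_hit_rate > 0 && n_decoy > 0L) {
      stats::rbinom(1L, n_decoy, truth$false_hit_rate)
    } else 0L
    if (n_false > 0L) {
      frid <- sprintf("%s_r%07d", sid, n_gene + sample.int(n_decoy, n_false))
      all_h <- unlist(hmm_ids)
      fh <- data.frame(read_id = frid, sample_id = sid,
                       hmm_id = all_h[sample.int(length(all_h), n_false,
                                                 replace = TRUE)],
                       evalue = 10^stats::runif(n_false, lo, hi),
                       stringsAsFactors = FALSE)
      prev_hmm <- if (s <= length(hmm_l)) hmm_l[[s]] else NULL
      prev_blast <- if (s <= length(blast_l)) blast_l[[s]] else NULL
      hmm_l[[s]] <- rbind(prev_hmm, fh)
      fb <- data.frame(
        read_id = rep(frid, each = 25L), sample_id = sid,
        rank = rep(1:25, n_false),
        subject_ko = kos[sample.int(length(kos), 25L * n_false,
                                    replace = TRUE)],
        bit_score = round(as.vector(
          apply(matrix(stats::runif(25L * n_false, 60, 300), 25L),
                2L, sort, decreasing = TRUE)), 1),
        stringsAsFactors = FALSE)
      blast_l[[s]] <- rbind(prev_blast, fb)
      # family labels of the spurious-hit reads (drawn from the trial
      # composition, consistent with the decoy family counts)
      ffam <- fams[sample.int(n_fam, n_false, replace = TRUE,
                              prob = shares)]
      fam_l[[s]] <- data.frame(read_id = frid, sample_id = sid,
                               family = ffam, stringsAsFactors = FALSE)
    }
  }

  truth_reads <- do.call(rbind, truth_l)
  if (is.null(truth_reads)) {
    truth_reads <- data.frame(read_id = character(), sample_id = character(),
                              gene = character(), family = character(),
                              stringsAsFactors = FALSE)
  }
  gene_fam <- truth_reads[c("read_id", "sample_id", "family")]
  gene_fam$family[gene_fam$family == "unclassified"] <- NA_character_
  read_family <- rbind(gene_fam, do.call(rbind, fam_l))
  read_family$family[which(read_family$family == "unclassified")] <- NA
  empty_df <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  hits_hmm <- do.call(rbind, hmm_l)
  if (is.null(hits_hmm)) {
    hits_hmm <- empty_df(read_id = character(), sample_id = character(),
                         hmm_id = character(), evalue = numeric())
  }
  hits_blast <- do.call(rbind, blast_l)
  if (is.null(hits_blast)) {
    hits_blast <- empty_df(read_id = character(), sample_id = character(),
                           rank = integer(), subject_ko = character(),
                           bit_score = numeric())
  }
  totals <- stats::setNames(rep(n_reads, nrow(samp)), samp$sample_id)
  structure(list(
    hits_hmm = hits_hmm, hits_blast = hits_blast,
    read_family = read_family, family_counts = fam_counts,
    totals = totals, truth_reads = truth_reads, samples = samp
  ), class = "synth_reads")
}

#' Write synthetic tables to tab-separated files
#'
#' Writes `hits_hmm.tsv`, `hits_blast.tsv`, `read_family.tsv`,
#' `metadata.tsv` and `truth.json` into a directory. With
#' `read_level = "all"` the read-to-family table covers every
#' bacterial read (Kaiju-like; large at realistic depths), with
#' `"hits"` only the reads occurring in the hit tables (the family
#' composition of all reads is then in `truth.json`).
#'
#' @param synth A `"synth_reads"` object.
#' @param metadata Metadata data.frame from [generate_metadata()].
#' @param dir Output directory (created if needed).
#' @param read_level `"hits"` (default) or `"all"`.
#' @param truth Optional [ground_truth()]; when given its parameters
#'   and ledger are stored in `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_synth <- function(synth, metadata, dir, read_level = c("hits", "all"),
                        truth = NULL) {
  read_level <- match.arg(read_level)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    data.table::fwrite(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       na = "")
  }
  wr(synth$hits_hmm, "hits_hmm.tsv")
  wr(synth$hits_blast, "hits_blast.tsv")
  if (read_level == "hits") {
    wr(synth$read_family, "read_family.tsv")
  } else {
    fam_all <- .materialise_read_family(synth)
    wr(fam_all, "read_family.tsv")
  }
  wr(metadata, "metadata.tsv")
  gc <- table(factor(synth$truth_reads$sample_id,
                     levels = synth$samples$sample_id))
  tr <- list(
    samples = synth$samples,
    gene_read_counts = stats::setNames(as.list(as.integer(gc)), names(gc)),
    family_counts = as.data.frame(synth$family_counts),
    totals = as.list(synth$totals)
  )
  if (!is.null(truth)) {
    tr$params <- truth[c("seed", "planted_gene_fraction", "gene_rates",
                         "p_agree", "unlabeled_rate", "false_hit_rate",
                         "evalue_range")]
    tr$effect_ledger <- truth$effect_ledger
  }
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# full Kaiju-like table: gene reads keep their drawn family, decoy
# reads are laid out deterministically from the decoy family counts
.materialise_read_family <- function(synth) {
  out <- vector("list", nrow(synth$samples))
  for (s in seq_len(nrow(synth$samples))) {
    sid <- synth$samples$sample_id[s]
    gene_rows <- synth$truth_reads[synth$truth_reads$sample_id == sid, ,
                                   drop = FALSE]
    n_gene <- nrow(gene_rows)
    decoy_counts <- synth$family_counts[sid, ]
    if (n_gene > 0L) {
      gf <- table(factor(gene_rows$family,
                         levels = colnames(synth$family_counts)))
      decoy_counts <- decoy_counts - as.integer(gf)
    }
    n_decoy <- sum(decoy_counts)
    fam <- c(gene_rows$family,
             rep(colnames(synth$family_counts), decoy_counts))
    fam[fam == "unclassified"] <- NA_character_
    out[[s]] <- data.frame(
      read_id = sprintf("%s_r%07d", sid, seq_len(n_gene + n_decoy)),
      sample_id = sid, family = fam, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
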