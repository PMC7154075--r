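#' Per-trial two-group tillage tests over features
#'
#' Runs the percentile-bootstrap two-group test ([pb_two_group()]) of
#' reduced vs conventional tillage on every feature (gene or family)
#' separately within each trial, and BH-adjusts the p-values within
#' each trial across features. The statistic is oriented RT - CT
#' (median difference), so positive values mean higher abundance under
#' reduced tillage.
#'
#' @param tab [abundance_table()] (or samples x features matrix) of
#'   the feature abundances.
#' @param metadata data.frame with `sample_id`, `trial`, `tillage`.
#' @param ct,rt Labels of the conventional and reduced tillage levels.
#' @param n_boot Bootstrap resamples per test (default 2000).
#' @param seed Master seed; the per-feature tests consume one RNG
#'   stream deterministically.
#' @param bh `"within-trial"` (default, adjust across features inside
#'   each trial) or `"global"` (across all trials jointly).
#' @return data.frame: `feature`, `trial`, `statistic`, `p`, `p_raw`,
#'   `q`, `effect_r`, `mean_ct`, `mean_rt`.
#' @export
tillage_tests_per_trial <- function(tab, metadata, ct = "CT", rt = "RT",
                                    n_boot = 2000, seed = NULL,
                                    bh = c("within-trial", "global")) {
  bh <- match.arg(bh)
  m <- if (inherits(tab, "abundance_table")) tab$values else as.matrix(tab)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$trial)) stop("metadata lacks rows for some samples")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (tr in unique(meta$trial)) {
    in_tr <- meta$trial == tr
    i_ct <- in_tr & meta$tillage == ct
    i_rt <- in_tr & meta$tillage == rt
    if (!any(i_ct) || !any(i_rt)) {
      stop("design error: trial ", tr, " lacks a tillage group")
    }
    res <- lapply(colnames(m), function(f) {
      tt <- pb_two_group(m[i_rt, f], m[i_ct, f], n_boot = n_boot)
      data.frame(feature = f, trial = tr, statistic = tt$statistic,
                 p = tt$p, p_raw = tt$p_raw, effect_r = tt$effect_r,
                 mean_ct = mean(m[i_ct, f]), mean_rt = mean(m[i_rt, f]),
                 stringsAsFactors = FALSE)
    })
    out[[tr]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (bh == "within-trial") {
    out$q <- stats::ave(out$p, out$trial, FUN = bh_adjust)
  } else {
    out$q <- bh_adjust(out$p)
  }
  out[c("feature", "trial", "statistic", "p", "p_raw", "q",
        "effect_r", "mean_ct", "mean_rt")]
}

#' Global two-way tests over features
#'
#' Runs the percentile-bootstrap robust two-way ANOVA
#' ([pb_two_way()]) of trial x tillage on every feature of an
#' abundance table and BH-adjusts p-values across features within
#' each factor.
#'
#' @inheritParams tillage_tests_per_trial
#' @return data.frame: `feature`, `factor` (`trial`, `tillage`,
#'   `interaction`), `statistic`, `p`, `p_raw`, `q`, `omega_sq`.
#' @export
global_tests <- function(tab, metadata, n_boot = 2000, seed = NULL) {
  m <- if (inherits(tab, "abundance_table")) tab$values else as.matrix(tab)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(colnames(m), function(f) {
    tw <- pb_two_way(m[, f], meta$trial, meta$tillage, n_boot = n_boot)
    data.frame(feature = f,
               factor = c("trial", "tillage", "interaction"),
               statistic = tw$statistic, p = tw$p, p_raw = tw$p_raw,
               omega_sq = tw$omega_sq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- stats::ave(out$p, out$factor, FUN = bh_adjust)
  out[c("feature", "factor", "statistic", "p", "p_raw", "q", "omega_sq")]
}

#' Classify tillage responders and partition them across trials
#'
#' A feature (family) is a responder in a trial iff its BH-adjusted
#' q-value there is at most `alpha`. Direction comes from the sign of
#' the RT - CT median difference; the log2 fold change is
#' `log2((mean_RT + eps) / (mean_CT + eps))` with pseudocount `eps` =
#' half the smallest nonzero value of the abundance table. The Venn
#' partition decomposes the responder sets of the trials into their
#' 2^k - 1 exclusive regions.
#'
#' @param tests Output of [tillage_tests_per_trial()].
#' @param tab The abundance table the tests were run on (for the
#'   pseudocount).
#' @param alpha Significance level on q (default 0.05).
#' @return List: `records` (data.frame `family`, `trial`, `q`,
#'   `direction`, `log2fc`, `mean_ct`, `mean_rt`) and `venn` (named
#'   counts of the exclusive regions, e.g. `"Frick&Juchowo"`).
#' @export
classify_responders <- function(tests, tab, alpha = 0.05) {
  m <- if (inherits(tab, "abundance_table")) tab$values else as.matrix(tab)
  pos <- m[m > 0]
  eps <- if (length(pos) > 0L) min(pos) / 2 else .Machine$double.eps
  hits <- tests[!is.na(tests$q) & tests$q <= alpha, , drop = FALSE]
  records <- data.frame(
    family = hits$feature, trial = hits$trial, q = hits$q,
    direction = ifelse(hits$statistic > 0, "RT-higher",
                       ifelse(hits$statistic < 0, "CT-higher", "none")),
    log2fc = log2((hits$mean_rt + eps) / (hits$mean_ct + eps)),
    mean_ct = hits$mean_ct, mean_rt = hits$mean_rt,
    stringsAsFactors = FALSE
  )
  records <- records[order(records$trial, -records$log2fc), , drop = FALSE]
  rownames(records) <- NULL
  sets <- split(records$family, factor(records$trial,
                                       levels = unique(tests$trial)))
  list(records = records, venn = venn_partition(sets))
}

#' Exclusive Venn partition of k sets
#'
#' Counts the elements falling in each non-empty intersection pattern
#' (exclusive regions: an element is counted in exactly one region).
#' Region names join the member set names with `&`.
#'
#' @param sets Named list of character vectors.
#' @return Named integer vector over the 2^k - 1 regions; the counts
#'   sum to the size of the union.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k == 0L) return(integer(0))
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_len(k))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  regions <- integer(0)
  for (size in seq_len(k)) {
    combos <- utils::combn(k, size, simplify = FALSE)
    for (cb in combos) {
      pattern <- seq_len(k) %in% cb
      cnt <- if (length(universe) == 0L) 0L else
        sum(apply(member, 1L, function(r) all(r == pattern)))
      regions[paste(nm[cb], collapse = "&")] <- cnt
    }
  }
  regions
}
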