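# Independent reference implementations and fixture builders used
# across the test files. The oracles are deliberately naive (explicit
# loops, exhaustive enumeration) and share no code with the package.

# --- naive consensus-KO reference -----------------------------------

# plain-loop re-statement of the assignment rule: best catalog HMM hit
# with e <= e_max gives the candidate; all KO-labelled hits among the
# top-k blast hits must equal it, and at least one must exist
naive_assign_ko <- function(record, catalog, e_max = 1e-5, k = 25) {
  hmm_map <- list()
  for (i in seq_len(nrow(catalog))) {
    for (h in strsplit(catalog$hmm_ids[i], ",")[[1]]) {
      hmm_map[[trimws(h)]] <- catalog$ko[i]
    }
  }
  best_e <- Inf; best_kos <- character(0); saw_catalog_hit <- FALSE
  hh <- record$hmm_hits
  if (!is.null(hh) && nrow(hh) > 0) {
    for (i in seq_len(nrow(hh))) {
      ko <- hmm_map[[hh$hmm_id[i]]]
      if (is.null(ko)) next
      saw_catalog_hit <- TRUE
      if (hh$evalue[i] > e_max) next
      if (hh$evalue[i] < best_e) {
        best_e <- hh$evalue[i]; best_kos <- ko
      } else if (hh$evalue[i] == best_e) {
        best_kos <- union(best_kos, ko)
      }
    }
  }
  if (!saw_catalog_hit) return(list(ko = NA, reason = "no-hmm-hit"))
  if (length(best_kos) == 0) return(list(ko = NA, reason = "evalue-fail"))
  if (length(best_kos) > 1) return(list(ko = NA, reason = "consensus-fail"))
  cand <- best_kos[1]
  bh <- record$blast_hits
  n_lab <- 0; all_agree <- TRUE
  if (!is.null(bh) && nrow(bh) > 0) {
    for (i in seq_len(min(k, nrow(bh)))) {
      s <- bh$subject_ko[i]
      if (is.na(s) || !nzchar(s)) next
      n_lab <- n_lab + 1
      if (s != cand) all_agree <- FALSE
    }
  }
  if (n_lab >= 1 && all_agree) list(ko = cand, reason = "assigned")
  else list(ko = NA, reason = "consensus-fail")
}

# random single-read fixture; coherent draws mimic a genuine gene read
# (HMM and aligner agreeing on one KO) so the assigned branch is
# exercised, incoherent draws scatter over all failure branches
random_record <- function(catalog) {
  hmm_map <- catalog_hmm_map(catalog)
  true_i <- sample(nrow(catalog), 1)
  true_ko <- catalog$ko[true_i]
  true_hmms <- hmm_map$hmm_id[hmm_map$ko == true_ko]
  coherent <- runif(1) < 0.6
  n_hmm <- sample(0:3, 1)
  hmm_pool <- c(hmm_map$hmm_id, "PF99999", "TIGR00001")
  hmm_hits <- if (n_hmm > 0) {
    ids <- if (coherent) {
      c(sample(true_hmms, 1), sample(hmm_pool, n_hmm - 1, replace = TRUE))
    } else {
      sample(hmm_pool, n_hmm, replace = TRUE)
    }
    data.frame(hmm_id = ids[seq_len(n_hmm)],
               evalue = 10^runif(n_hmm, -12, -2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(hmm_id = character(0), evalue = numeric(0))
  }
  n_blast <- sample(c(0, 5, 25, 30), 1)
  blast_hits <- if (n_blast > 0) {
    ko <- if (coherent) {
      k <- rep(true_ko, n_blast)
      k[runif(n_blast) < 0.1] <- NA            # unlabelled subjects
      n_bad <- rbinom(1, 1, 0.3)
      if (n_bad > 0) k[sample(n_blast, n_bad)] <-
          sample(setdiff(catalog$ko, true_ko), n_bad)
      k
    } else {
      sample(c(catalog$ko, NA), n_blast, replace = TRUE,
             prob = c(rep(1, nrow(catalog)), 4))
    }
    data.frame(subject_ko = ko,
               bit_score = sort(runif(n_blast, 50, 300), decreasing = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(subject_ko = character(0), bit_score = numeric(0))
  }
  list(read_id = "r1", sample_id = "s1",
       hmm_hits = hmm_hits, blast_hits = blast_hits)
}

# --- exhaustive rarefaction oracle ----------------------------------

# expected richness by enumerating all C(N, n) subsamples (N <= ~10)
enum_rarefaction <- function(counts, n) {
  reads <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(reads), n)
  mean(apply(subsets, 2, function(ix) length(unique(reads[ix]))))
}

# --- small synthetic study shared by several files ------------------

small_config <- function(seed = 11, effects = NULL, n_boot = 200,
                         reads = 5e4) {
  pipeline_config(
    design = study_design(reads_per_sample = reads),
    seed = seed, effects = effects, detection = "calibrated",
    n_boot = n_boot, n_tail_families = 10
  )
}
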