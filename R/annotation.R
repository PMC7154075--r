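## Consensus KO assignment: a read keeps the KO of its best profile-HMM
## hit (E-value <= 1e-5, HMM in the catalog) only when the KO-labelled
## hits among its best 25 protein-aligner hits unanimously agree.

#' Parse tab-separated hit tables into a read-hits object
#'
#' Reads three tab-separated tables with one-line headers:
#' \describe{
#'   \item{hmm_file}{HMMER-tblout-like: `read_id`, `sample_id`,
#'     `hmm_id`, `evalue`.}
#'   \item{blast_file}{BLAST/DIAMOND-outfmt6-like: `read_id`,
#'     `sample_id`, `rank` (1-based, best first), `subject_ko` (empty
#'     when the subject has no KO label), `bit_score`.}
#'   \item{family_file}{Kaiju-like read-to-family map: `read_id`,
#'     `sample_id`, `family`.}
#' }
#' Reads present only in the family table get empty hit lists. Blast
#' hits with equal bit scores keep their file order (encoded in
#' `rank`). When a catalog is supplied, HMM identifiers outside it
#' trigger a warning but the hits are retained.
#'
#' @param hmm_file,blast_file,family_file Paths to the three tables.
#' @param catalog Optional catalog for the unknown-HMM warning.
#' @return An object of class `"read_hits"`: list of data.frames
#'   `hmm`, `blast`, `reads` (read_id, sample_id, family).
#' @export
parse_hit_tables <- function(hmm_file, blast_file, family_file,
                             catalog = NULL) {
  hmm <- .read_tsv(hmm_file,
                   c(read_id = "character", sample_id = "character",
                     hmm_id = "character", evalue = "numeric"))
  blast <- .read_tsv(blast_file,
                     c(read_id = "character", sample_id = "character",
                       rank = "integer", subject_ko = "character",
                       bit_score = "numeric"))
  fam <- .read_tsv(family_file,
                   c(read_id = "character", sample_id = "character",
                     family = "character"))
  if (!is.null(catalog)) {
    known <- catalog_hmm_map(catalog)$hmm_id
    unk <- setdiff(unique(hmm$hmm_id), known)
    if (length(unk) > 0L) {
      warning("hmm hits with identifiers outside the catalog retained: ",
              paste(unk, collapse = ", "))
    }
  }
  structure(list(hmm = hmm, blast = blast, reads = fam),
            class = "read_hits")
}

.read_tsv <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = NA, na.strings = c("NA", "")),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e))
  )
  missing <- setdiff(names(col_types), names(df))
  if (length(missing) > 0L) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df <- df[names(col_types)]
  for (nm in names(col_types)) {
    cls <- col_types[[nm]]
    if (cls == "numeric" || cls == "integer") {
      conv <- suppressWarnings(as.numeric(df[[nm]]))
      bad <- which(is.na(conv) & !is.na(df[[nm]]))
      if (length(bad) > 0L) {
        stop("parse error in ", path, " line ", bad[1L] + 1L,
             ": non-numeric value in column ", nm)
      }
      na <- which(is.na(conv))
      if (nm != "subject_ko" && length(na) > 0L) {
        stop("parse error in ", path, " line ", na[1L] + 1L,
             ": missing value in column ", nm)
      }
      df[[nm]] <- if (cls == "integer") as.integer(conv) else conv
    }
  }
  df
}

#' Assign a KO number to a single read
#'
#' Implements the consensus rule: the candidate KO is the KO of the
#' best (lowest E-value) HMM hit with `e_value <= e_max` whose HMM is
#' in the catalog; the read is assigned that KO iff at least one
#' KO-labelled hit occurs among the top-`k` blast hits and (under the
#' default unanimity rule) every labelled hit there equals the
#' candidate. Otherwise the read is UNASSIGNED with a reason code:
#' \describe{
#'   \item{no-hmm-hit}{no HMM hit matching a catalog HMM at all;}
#'   \item{evalue-fail}{catalog HMM hits exist but all E-values exceed
#'     `e_max`;}
#'   \item{consensus-fail}{a candidate exists but the blast consensus
#'     fails (no labelled hit in the top k, a discordant labelled hit,
#'     or an exact E-value tie between catalog HMMs mapping to
#'     different KOs).}
#' }
#' Blast hits whose subjects lack a KO label are ignored in the
#' consensus by default; `strict_unlabeled = TRUE` makes them veto the
#' assignment. `rule = "majority"` replaces unanimity by a strict
#' majority of the labelled top-k hits.
#'
#' @param record List with `read_id`, `sample_id`, `hmm_hits`
#'   (data.frame `hmm_id`, `evalue`) and `blast_hits` (data.frame
#'   `subject_ko`, `bit_score`, ordered best-first).
#' @param catalog Gene catalog (see [load_catalog()]).
#' @param e_max Maximum HMM E-value, default 1e-5.
#' @param k Number of top blast hits consulted, default 25.
#' @param rule `"unanimity"` (default) or `"majority"`.
#' @param strict_unlabeled Treat unlabelled blast hits as discordant.
#' @return One-row data.frame: `read_id`, `sample_id`, `ko` (NA when
#'   unassigned), `reason`.
#' @export
assign_ko <- function(record, catalog = eps_lps_catalog(), e_max = 1e-5,
                      k = 25, rule = c("unanimity", "majority"),
                      strict_unlabeled = FALSE) {
  rule <- match.arg(rule)
  if (e_max <= 0) stop("e_max must be positive")
  if (k < 1) stop("k must be >= 1")
  hmm_map <- catalog_hmm_map(catalog)
  hh <- record$hmm_hits
  res <- function(ko, reason) {
    data.frame(read_id = record$read_id, sample_id = record$sample_id,
               ko = ko, reason = reason, stringsAsFactors = FALSE)
  }
  if (is.null(hh) || nrow(hh) == 0L) return(res(NA_character_, "no-hmm-hit"))
  hh$ko <- hmm_map$ko[match(hh$hmm_id, hmm_map$hmm_id)]
  hh <- hh[!is.na(hh$ko), , drop = FALSE]
  if (nrow(hh) == 0L) return(res(NA_character_, "no-hmm-hit"))
  hh <- hh[hh$evalue <= e_max, , drop = FALSE]
  if (nrow(hh) == 0L) return(res(NA_character_, "evalue-fail"))
  best <- hh[hh$evalue == min(hh$evalue), , drop = FALSE]
  if (length(unique(best$ko)) > 1L) {
    return(res(NA_character_, "consensus-fail"))  # exact E-value tie
  }
  cand <- best$ko[1L]
  bh <- record$blast_hits
  if (is.null(bh) || nrow(bh) == 0L) return(res(NA_character_, "consensus-fail"))
  top <- utils::head(bh, k)
  labelled <- top$subject_ko[!is.na(top$subject_ko) & nzchar(top$subject_ko)]
  if (length(labelled) == 0L) return(res(NA_character_, "consensus-fail"))
  if (strict_unlabeled && length(labelled) < nrow(top)) {
    return(res(NA_character_, "consensus-fail"))
  }
  ok <- if (rule == "unanimity") {
    all(labelled == cand)
  } else {
    sum(labelled == cand) > length(labelled) / 2
  }
  if (ok) res(cand, "assigned") else res(NA_character_, "consensus-fail")
}

#' Assign KO numbers to all reads of a read-hits object
#'
#' Vectorised application of the [assign_ko()] consensus rule to every
#' read in a `"read_hits"` object (the union of reads in the family
#' table and the hit tables). Identical in outcome to calling
#' [assign_ko()] per read.
#'
#' @param hits A `"read_hits"` object (see [parse_hit_tables()]), or a
#'   list with data.frames `hmm`, `blast`, `reads` in the same layout.
#' @inheritParams assign_ko
#' @return data.frame with one row per read: `read_id`, `sample_id`,
#'   `ko`, `reason`.
#' @export
assign_reads <- function(hits, catalog = eps_lps_catalog(), e_max = 1e-5,
                         k = 25, rule = c("unanimity", "majority"),
                         strict_unlabeled = FALSE) {
  rule <- match.arg(rule)
  if (e_max <= 0) stop("e_max must be positive")
  if (k < 1) stop("k must be >= 1")
  hmm_map <- catalog_hmm_map(catalog)

  uid <- function(r, s) paste(r, s, sep = "\r")
  all_ids <- unique(c(uid(hits$reads$read_id, hits$reads$sample_id),
                      uid(hits$hmm$read_id, hits$hmm$sample_id),
                      uid(hits$blast$read_id, hits$blast$sample_id)))

  hmm <- data.table::as.data.table(hits$hmm)
  hmm[, ko := hmm_map$ko[match(hmm_id, hmm_map$hmm_id)]]
  hmm <- hmm[!is.na(ko)]
  hmm[, id := uid(read_id, sample_id)]
  has_catalog_hmm <- unique(hmm$id)
  pass <- hmm[evalue <= e_max]
  cand <- pass[, {
    b <- .SD[evalue == min(evalue)]
    list(ko = if (length(unique(b$ko)) == 1L) b$ko[1L] else NA_character_)
  }, by = id]
  # NA candidate = exact tie across KOs -> consensus-fail

  blast <- data.table::as.data.table(hits$blast)
  blast[, id := uid(read_id, sample_id)]
  data.table::setorder(blast, id, rank)
  blast[, in_top := seq_len(.N) <= k, by = id]
  top <- blast[in_top == TRUE]
  top[, cand_ko := cand$ko[match(id, cand$id)]]
  top[, labelled := !is.na(subject_ko) & nzchar(subject_ko)]
  cons <- top[, list(
    n_top = .N,
    n_lab = sum(labelled),
    n_match = sum(labelled & !is.na(cand_ko) & subject_ko == cand_ko)
  ), by = id]

  out <- data.table::data.table(id = all_ids)
  parts <- data.table::tstrsplit(out$id, "\r", fixed = TRUE)
  out[, read_id := parts[[1L]]]
  out[, sample_id := parts[[2L]]]
  out[, ko := cand$ko[match(id, cand$id)]]
  out[, reason := "no-hmm-hit"]
  out[id %in% has_catalog_hmm, reason := "evalue-fail"]
  out[id %in% cand$id, reason := "consensus-fail"]
  out <- merge(out, cons, by = "id", all.x = TRUE, sort = FALSE)
  out[is.na(n_lab), n_lab := 0L]
  out[is.na(n_match), n_match := 0L]
  out[is.na(n_top), n_top := 0L]
  agreed <- out$reason == "consensus-fail" & !is.na(out$ko) &
    out$n_lab > 0L &
    (if (rule == "unanimity") out$n_match == out$n_lab
     else out$n_match > out$n_lab / 2) &
    (!strict_unlabeled | out$n_lab == out$n_top)
  out[agreed, reason := "assigned"]
  out[reason != "assigned", ko := NA_character_]
  res <- as.data.frame(out[, list(read_id, sample_id, ko, reason)])
  res <- res[order(res$sample_id, res$read_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exclude genes with too little read support
#'
#' Mirrors the study's exclusion of sparsely covered genes (a handful
#' of reads, mostly in single replicates): a gene is excluded iff its
#' total assigned reads fall below `min_reads` or it occurs in fewer
#' than `min_samples` samples.
#'
#' @param assignments Assignment data.frame (see [assign_reads()]).
#' @param min_reads Minimum total assigned reads (default 10).
#' @param min_samples Minimum number of samples with >= 1 read
#'   (default 2).
#' @param catalog Gene catalog; genes without any assigned read are
#'   reported as excluded too.
#' @return List with `retained` (character vector of gene names) and
#'   `excluded` (data.frame `gene`, `n_reads`, `n_samples`).
#' @export
filter_low_support_genes <- function(assignments, min_reads = 10,
                                     min_samples = 2,
                                     catalog = eps_lps_catalog()) {
  if (min_reads < 1) stop("min_reads must be >= 1")
  if (min_samples < 1) stop("min_samples must be >= 1")
  if (nrow(assignments) == 0L) stop("no assignments")
  asg <- assignments[assignments$reason == "assigned", , drop = FALSE]
  gene <- catalog$gene[match(asg$ko, catalog$ko)]
  n_reads <- vapply(catalog$gene,
                    function(g) sum(gene == g, na.rm = TRUE), integer(1))
  n_samples <- vapply(catalog$gene, function(g) {
    length(unique(asg$sample_id[which(gene == g)]))
  }, integer(1))
  keep <- n_reads >= min_reads & n_samples >= min_samples
  list(
    retained = catalog$gene[keep],
    excluded = data.frame(gene = catalog$gene[!keep],
                          n_reads = n_reads[!keep],
                          n_samples = n_samples[!keep],
                          row.names = NULL, stringsAsFactors = FALSE)
  )
}
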