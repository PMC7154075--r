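cat12 <- eps_lps_catalog()

mk_record <- function(hmm = NULL, blast = NULL) {
  list(read_id = "r1", sample_id = "s1",
       hmm_hits = if (is.null(hmm))
         data.frame(hmm_id = character(0), evalue = numeric(0)) else hmm,
       blast_hits = if (is.null(blast))
         data.frame(subject_ko = character(0), bit_score = numeric(0))
       else blast)
}

test_that("assign_ko applies the E-value cutoff and best-25 unanimity", {
  top25 <- function(kos) data.frame(subject_ko = kos,
                                    bit_score = seq(300, by = -1,
                                                    length.out = length(kos)))
  # E-value above the 1e-5 cutoff
  r <- assign_ko(mk_record(data.frame(hmm_id = "PF02563", evalue = 1e-4),
                           top25(rep("K01991", 25))), cat12)
  expect_equal(r$reason, "evalue-fail")
  expect_true(is.na(r$ko))
  # unanimous top-25 agreement
  r <- assign_ko(mk_record(data.frame(hmm_id = "PF02563", evalue = 1e-8),
                           top25(rep("K01991", 25))), cat12)
  expect_equal(r$reason, "assigned")
  expect_equal(r$ko, "K01991")
  # one discordant hit among 25 vetoes the assignment
  r <- assign_ko(mk_record(data.frame(hmm_id = "PF02563", evalue = 1e-8),
                           top25(c(rep("K01991", 24), "K03819"))), cat12)
  expect_equal(r$reason, "consensus-fail")
  # exactly at the threshold is accepted ("maximum E-value of 1e-5")
  r <- assign_ko(mk_record(data.frame(hmm_id = "PF02563", evalue = 1e-5),
                           top25(rep("K01991", 25))), cat12)
  expect_equal(r$reason, "assigned")
  # no HMM hit at all / only non-catalog HMMs
  expect_equal(assign_ko(mk_record(), cat12)$reason, "no-hmm-hit")
  r <- assign_ko(mk_record(data.frame(hmm_id = "PF99999", evalue = 1e-9),
                           top25(rep("K01991", 25))), cat12)
  expect_equal(r$reason, "no-hmm-hit")
  # unlabelled hits are ignored by default but veto under strictness
  mixed <- top25(c(rep("K01991", 10), rep(NA, 15)))
  rec <- mk_record(data.frame(hmm_id = "PF02563", evalue = 1e-8), mixed)
  expect_equal(assign_ko(rec, cat12)$reason, "assigned")
  expect_equal(assign_ko(rec, cat12, strict_unlabeled = TRUE)$reason,
               "consensus-fail")
  # all-unlabelled top-k: no labelled hit exists, no assignment
  rec <- mk_record(data.frame(hmm_id = "PF02563", evalue = 1e-8),
                   top25(rep(NA_character_, 25)))
  expect_equal(assign_ko(rec, cat12)$reason, "consensus-fail")
  # exact E-value tie between HMMs mapping to different KOs
  rec <- mk_record(data.frame(hmm_id = c("PF02563", "TIGR04016"),
                              evalue = c(1e-8, 1e-8)),
                   top25(rep("K01991", 25)))
  expect_equal(assign_ko(rec, cat12)$reason, "consensus-fail")
  # majority rule accepts 24/25 agreement
  rec <- mk_record(data.frame(hmm_id = "PF02563", evalue = 1e-8),
                   top25(c(rep("K01991", 24), "K03819")))
  expect_equal(assign_ko(rec, cat12, rule = "majority")$reason, "assigned")
})

test_that("lowering e_max or raising k never flips the assigned KO", {
  set.seed(7)
  n_both <- 0L
  for (i in 1:200) {
    rec <- random_record(cat12)
    loose <- assign_ko(rec, cat12, e_max = 1e-4, k = 10)
    strict <- assign_ko(rec, cat12, e_max = 1e-6, k = 25)
    if (loose$reason == "assigned" && strict$reason == "assigned") {
      n_both <- n_both + 1L
      expect_identical(loose$ko, strict$ko)
    }
  }
  expect_gt(n_both, 0L)  # the property was actually exercised
})

test_that("vectorised assignment equals the per-record rule", {
  set.seed(21)
  cfg <- small_config(seed = 21, reads = 2e4)
  synth <- generate_read_tables(cfg$design, cfg$truth)
  hits <- structure(list(hmm = synth$hits_hmm, blast = synth$hits_blast,
                         reads = synth$read_family), class = "read_hits")
  vec <- assign_reads(hits, cat12)
  ids <- paste(vec$read_id, vec$sample_id)
  pick <- sample(nrow(vec), 50)
  for (i in pick) {
    rid <- vec$read_id[i]; sid <- vec$sample_id[i]
    hh <- synth$hits_hmm[synth$hits_hmm$read_id == rid &
                           synth$hits_hmm$sample_id == sid,
                         c("hmm_id", "evalue")]
    bh <- synth$hits_blast[synth$hits_blast$read_id == rid &
                             synth$hits_blast$sample_id == sid, ]
    bh <- bh[order(bh$rank), c("subject_ko", "bit_score")]
    single <- assign_ko(list(read_id = rid, sample_id = sid,
                             hmm_hits = hh, blast_hits = bh), cat12)
    expect_equal(vec$reason[i], single$reason)
    expect_equal(vec$ko[i], single$ko)
  }
})

test_that("hit tables round-trip through files", {
  cfg <- small_config(seed = 5, reads = 5e3)
  md <- generate_metadata(cfg$design, cfg$truth)
  synth <- generate_read_tables(cfg$design, cfg$truth)
  dir <- withr::local_tempdir()
  write_synth(synth, md, dir, read_level = "all", truth = cfg$truth)
  hits <- parse_hit_tables(file.path(dir, "hits_hmm.tsv"),
                           file.path(dir, "hits_blast.tsv"),
                           file.path(dir, "read_family.tsv"),
                           catalog = cat12)
  expect_s3_class(hits, "read_hits")
  # all bacterial reads of the design appear in the family table
  expect_equal(nrow(hits$reads), 18 * 5e3)
  parsed <- assign_reads(hits, cat12)
  direct <- assign_reads(structure(list(hmm = synth$hits_hmm,
                                        blast = synth$hits_blast,
                                        reads = synth$read_family),
                                   class = "read_hits"), cat12)
  parsed_hit <- parsed[!is.na(parsed$ko), ]
  direct_hit <- direct[!is.na(direct$ko), ]
  expect_equal(parsed_hit[order(parsed_hit$read_id), "ko"],
               direct_hit[order(direct_hit$read_id), "ko"])
  # malformed numeric cell is reported with file and line
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("read_id\tsample_id\thmm_id\tevalue",
               "r1\ts1\tPF02563\tnot_a_number"), bad)
  expect_error(parse_hit_tables(bad, file.path(dir, "hits_blast.tsv"),
                                file.path(dir, "read_family.tsv")),
               "bad.tsv line 2")
  # unknown HMM ids warn but are retained
  unk <- file.path(dir, "unk.tsv")
  writeLines(c("read_id\tsample_id\thmm_id\tevalue",
               "r1\ts1\tPF00000\t1e-9"), unk)
  expect_warning(h <- parse_hit_tables(unk, file.path(dir, "hits_blast.tsv"),
                                       file.path(dir, "read_family.tsv"),
                                       catalog = cat12),
                 "PF00000")
  expect_equal(nrow(h$hmm), 1L)
})

test_that("low-support genes are excluded like epsA/epsG were", {
  mk_asg <- function(gene_counts, samples_per_gene) {
    rows <- list()
    for (g in names(gene_counts)) {
      n <- gene_counts[[g]]
      ko <- cat12$ko[match(g, cat12$gene)]
      sids <- rep_len(paste0("s", seq_len(samples_per_gene[[g]])), n)
      rows[[g]] <- data.frame(read_id = paste0(g, seq_len(n)),
                              sample_id = sids, ko = ko,
                              reason = "assigned")
    }
    do.call(rbind, rows)
  }
  # a 7-read single-replicate gene is dropped, an abundant one kept
  asg <- mk_asg(list(wza = 700, algJ = 7), list(wza = 18, algJ = 1))
  res <- filter_low_support_genes(asg)
  expect_true("wza" %in% res$retained)
  expect_true("algJ" %in% res$excluded$gene)
  expect_equal(res$excluded$n_reads[res$excluded$gene == "algJ"], 7L)
  # permissive limits retain any gene with one read
  res <- filter_low_support_genes(mk_asg(list(sacB = 1), list(sacB = 1)),
                                  min_reads = 1, min_samples = 1)
  expect_true("sacB" %in% res$retained)
  # no assigned reads at all: everything excluded
  none <- data.frame(read_id = "r1", sample_id = "s1",
                     ko = NA_character_, reason = "no-hmm-hit")
  res <- filter_low_support_genes(none)
  expect_equal(length(res$retained), 0L)
  expect_equal(nrow(res$excluded), 12L)
  expect_error(filter_low_support_genes(asg, min_reads = 0), "min_reads")
})
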