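test_that("zero-noise metadata reproduces the site means exactly", {
  d <- study_design(reads_per_sample = 1000)
  tr <- ground_truth(d, seed = 3,
                     cmic_model = list(
                       site_means = epslps:::.default_site_means(),
                       tillage_deltas = epslps:::.default_tillage_deltas(),
                       noise_cv = 0))
  md <- generate_metadata(d, tr)
  expect_equal(nrow(md), 18L)
  means <- tapply(md$Cmic, md$trial, mean)
  expect_equal(as.numeric(means[c("Frick", "Moskanjci", "Juchowo")]),
               c(1341.9, 342.2, 121.5))
  expect_equal(as.numeric(tapply(md$Nmic, md$trial, mean)[
    c("Frick", "Moskanjci", "Juchowo")]), c(191.3, 53.0, 18.5))
  # covariates named in the soil table are all present
  expect_true(all(c("clay", "silt", "sand", "SAF", "Corg", "DOC", "DON",
                    "pH", "Cmic", "Nmic", "Cmic_Nmic") %in% names(md)))
  expect_true(all(md$Cmic_Nmic > 0))
  # Cmic responds to tillage within each trial, SAF only at the loamy site
  by_cell <- tapply(md$Cmic, list(md$trial, md$tillage), mean)
  expect_true(all(by_cell[, "RT"] > by_cell[, "CT"]))
  saf <- tapply(md$SAF, list(md$trial, md$tillage), mean)
  expect_gt(saf["Moskanjci", "RT"], saf["Moskanjci", "CT"])
  expect_equal(saf["Frick", "RT"], saf["Frick", "CT"])
})

test_that("a minimal design yields a single-row table", {
  d <- study_design(trials = "Frick", tillage = "CT", replicates = 1,
                    reads_per_sample = 100)
  md <- generate_metadata(d, ground_truth(d, seed = 1))
  expect_equal(nrow(md), 1L)
})

test_that("generation is deterministic in the seed", {
  d <- study_design(reads_per_sample = 5e3)
  t7a <- ground_truth(d, seed = 7); t7b <- ground_truth(d, seed = 7)
  t8 <- ground_truth(d, seed = 8)
  expect_identical(generate_metadata(d, t7a), generate_metadata(d, t7b))
  expect_false(identical(generate_metadata(d, t7a),
                         generate_metadata(d, t8)))
  sa <- generate_read_tables(d, t7a); sb <- generate_read_tables(d, t7b)
  expect_identical(sa$hits_hmm, sb$hits_hmm)
  expect_identical(sa$hits_blast, sb$hits_blast)
  expect_identical(sa$family_counts, sb$family_counts)
  # written files are byte-identical
  md <- generate_metadata(d, t7a)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth(sa, md, d1, read_level = "all", truth = t7a)
  write_synth(sb, md, d2, read_level = "all", truth = t7b)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("reads are conserved and zero signal yields empty tables", {
  d <- study_design(reads_per_sample = 2e4)
  tr <- ground_truth(d, seed = 2)
  s <- generate_read_tables(d, tr)
  # gene reads + decoy reads = reads_per_sample in every sample
  expect_true(all(rowSums(s$family_counts) == 2e4))
  expect_equal(unname(s$totals), rep(2e4, 18))
  # no planted genes, no false hits: no hit records at all
  tr0 <- ground_truth(d, seed = 2, planted_gene_fraction = 0,
                      false_hit_rate = 0)
  s0 <- generate_read_tables(d, tr0)
  expect_equal(nrow(s0$hits_hmm), 0L)
  expect_equal(nrow(s0$hits_blast), 0L)
  expect_equal(nrow(s0$truth_reads), 0L)
  expect_true(all(rowSums(s0$family_counts) == 2e4))
})

test_that("parameter validation rejects impossible truths", {
  d <- study_design(reads_per_sample = 100)
  expect_error(ground_truth(d, p_agree = 1.2), "p_agree")
  expect_error(ground_truth(d, effect_ledger = data.frame(
    feature = "wza", type = "gene", trial = "Frick", tillage = "RT",
    effect = -1)), "effects must be > 0")
  sm <- epslps:::.default_site_means(); sm$Cmic[1] <- -10
  expect_error(ground_truth(d, cmic_model = list(
    site_means = sm, tillage_deltas = epslps:::.default_tillage_deltas(),
    noise_cv = 0.05)), "non-positive Cmic")
  expect_error(study_design(replicates = 0), "replicates")
})

test_that("assigned gene fraction recovers the planted 0.033% under calibrated detection", {
  d <- study_design(trials = "Frick", replicates = 1,
                    reads_per_sample = 1e6)
  tr <- ground_truth(d, seed = 31, evalue_range = c(1e-12, 1e-6),
                     p_agree = 1, false_hit_rate = 0)
  s <- generate_read_tables(d, tr)
  asg <- assign_reads(structure(list(hmm = s$hits_hmm, blast = s$hits_blast,
                                     reads = s$read_family),
                                class = "read_hits"))
  frac <- sum(asg$reason == "assigned") / sum(s$totals)
  se <- sqrt(3.3e-4 * (1 - 3.3e-4) / sum(s$totals))
  expect_lt(abs(frac - 3.3e-4), 3 * se)
})

test_that("planted tillage effects materialise as the ledger ratio", {
  led <- data.frame(feature = "Bradyrhizobiaceae", type = "family",
                    trial = "Frick", tillage = "RT", effect = 2)
  d <- study_design(trials = "Frick", reads_per_sample = 4e6)
  tr <- ground_truth(d, seed = 13, effect_ledger = led)
  s <- generate_read_tables(d, tr)
  tru <- s$truth_reads
  fam_reads <- tru[tru$family == "Bradyrhizobiaceae", ]
  till <- s$samples$tillage[match(fam_reads$sample_id,
                                  s$samples$sample_id)]
  n_rt <- sum(till == "RT"); n_ct <- sum(till == "CT")
  # realized RT:CT gene-read ratio within 3 SE (log scale) of the
  # planted 2x effect
  se_log <- sqrt(1 / n_rt + 1 / n_ct)
  expect_lt(abs(log(n_rt / n_ct) - log(2)), 3 * se_log)
  # untouched family unaffected
  oth <- tru[tru$family == "Streptomycetaceae", ]
  till_o <- s$samples$tillage[match(oth$sample_id, s$samples$sample_id)]
  r_o <- sum(till_o == "RT") / sum(till_o == "CT")
  expect_lt(abs(log(r_o)), 3 * sqrt(1 / sum(till_o == "RT") +
                                      1 / sum(till_o == "CT")))
})
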