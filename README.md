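# epslps

Targeted metagenomic profiling of the bacterial potential to produce
soil-aggregating exopolysaccharides (EPS) and lipopolysaccharides
(LPS) under different tillage intensities.

## The problem

Soil aggregates are stabilised in part by bacterial polysaccharides
that glue mineral particles together. Shotgun soil metagenomes let us
ask whether reduced tillage (RT) favours this potential over
conventional ploughing (CT), and whether the answer depends on the
site: count the reads carrying EPS/LPS biosynthesis marker genes,
express them per bacterial read, scale them by microbial biomass
carbon (Cmic), and test site and tillage effects with robust
statistics suited to three replicate plots per treatment.

`epslps` is for microbiome researchers who have per-read annotation
tables (profile-HMM hits, protein-aligner hits, taxonomic
classifications) from such a study — or who want to validate the
analysis logic itself on synthetic data with known planted effects,
which the package generates.

## What it computes

- **Consensus KO assignment.** A read is assigned the KEGG Orthology
  number of its best catalog HMM hit (E-value <= 1e-5) only when the
  KO-labelled hits among its best 25 aligner hits unanimously agree.
  The built-in catalog covers 12 genes (8 EPS, e.g. *wza*/K01991;
  4 LPS, e.g. *lptF*/K07091). Genes with fewer than 10 reads or seen
  in fewer than 2 samples are excluded before inference.
- **Abundances.** Relative abundance = 100 x reads / total bacterial
  reads; absolute abundance = relative% x Cmic / 100 (mg biomass-C per
  kg soil); family x gene profiles; exact hypergeometric rarefaction
  E[S_n] = sum_g (1 - C(N-N_g, n)/C(N, n)).
- **Robust inference.** Percentile-bootstrap tests on medians (2000
  resamples): two-way trial x tillage ANOVA via sums of squared
  contrasts of cell medians with a within-cell centred bootstrap
  null, and per-trial two-group tillage tests with
  p = 2 min(p*, 1-p*), p* = (#{d*>0} + 0.5#{d*=0})/B.
  Benjamini-Hochberg FDR across features; omega-squared and Pearson-r
  effect sizes.
- **Ordination and responders.** PCA of soil covariates; Bray-Curtis
  PCoA with the Cailliez additive constant (computed from the 2n x 2n
  companion eigenproblem, reported explicitly); 95% confidence
  ellipses; responder families (q <= 0.05 within trial) with RT/CT
  log2 fold changes and their cross-trial Venn partition.
- **Soil variables.** Chloroform-fumigation microbial biomass
  (flush / kEC with kEC = 0.45, kEN = 0.54) and the sand-corrected
  stable aggregate fraction 100(retained - sand)/(initial - sand).
- **Synthetic studies.** `study_design()` + `ground_truth()` +
  `generate_read_tables()` emulate the full 3-trial x 2-tillage x
  3-replicate design (~2.8e6 bacterial reads/sample, 385-family
  community, 0.033% gene-carrying reads) with a planted-effect ledger
  and exact reproducibility from one seed.

## Worked example

```r
library(epslps)

cfg <- pipeline_config(
  design    = study_design(reads_per_sample = 2.8e6),
  seed      = 1,
  effects   = study_effects_ledger(),   # planted site-specific tillage responses
  detection = "calibrated"              # hit tables as if already threshold-filtered
)
res <- run_pipeline(cfg)
res
#> EPS/LPS profiling pipeline run (seed 1)
#>   18 samples x 2,800,000 reads; 16744 gene reads assigned (0.0332% of bacterial reads)
#>   genes retained: 12 of 12; families carrying genes: 225/385 (58.4%)
#>   tillage-affected genes per trial (%): Frick 33.3, Moskanjci 66.7, Juchowo 0.0
#>   responder families per trial: Frick 19, Moskanjci 50, Juchowo 13
```

Reading this: of 50.4 million synthetic bacterial reads, 16,744 were
assigned to the 12-gene catalog — 0.0332%, matching the planted
0.033% because the calibrated detection model emulates
already-filtered hit tables. All 12 genes survive the low-support
filter at this depth. The per-trial percentages are the share of
retained genes whose abundance differs between tillage treatments at
BH-adjusted q <= 0.05; the planted truth is 3/12 (25%) at Frick, 8/12
(66.7%) at Moskanjci and 1/12 (8.3%) at Juchowo, and the flagged sets
scatter around that truth with roughly one-gene noise — with three
replicate plots per group the percentile bootstrap is coarse, which
is exactly what the synthetic study is there to make visible.

```r
res$ordinations$families
#> PCoA ordination: 18 samples, 16 retained axes
#> variance explained: 64.1%, 28.9%, 0.9%, 0.8%
#> Cailliez constant: 0.00327525
```

The two leading axes separate the three sites, mirroring the soil
PCA; the small Cailliez constant says the Bray-Curtis matrix was
nearly Euclidean.

The `analysis/` directory holds the same workflow as five numbered
stage scripts (simulate, annotate, abundance, statistics, ordination)
that write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1 && Rscript analysis/02_annotate.R \
  && Rscript analysis/03_abundance.R && Rscript analysis/04_stats.R 1 \
  && Rscript analysis/05_ordination.R
```

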