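---
title: "Profiling EPS/LPS biosynthesis potential under tillage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling EPS/LPS biosynthesis potential under tillage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Bacteria stabilise soil aggregates by exuding exopolysaccharides (EPS)
and carrying lipopolysaccharides (LPS) that glue mineral particles
together. Whether reduced tillage (RT, shallow non-inversion loosening)
favours this microbial "gluing" potential over conventional mouldboard
ploughing (CT) — and whether the answer depends on the site — can be
asked of shotgun soil metagenomes: count the reads carrying marker
genes of EPS/LPS biosynthesis and export, express them per bacterial
read, scale them by microbial biomass, and test for site and tillage
effects with statistics that tolerate tiny, skewed samples.

`epslps` implements that complete analysis as a reusable, tested
pipeline, together with a synthetic-data generator that plants known
site and tillage effects so every stage can be validated without any
sequencing data.

## The gene catalog and the consensus assignment rule

Twelve marker genes are profiled (8 EPS, 4 LPS), each identified by a
KEGG Orthology (KO) number and one or two TIGRFAMs/Pfam profile HMMs —
for example *wza* (polysaccharide export, K01991, PF02563) and the
LPS-export complex genes *lptC/F/G*. Assignment of a read is
deliberately conservative, combining two independent lines of
evidence:

1. **HMM filter.** The candidate KO is the KO of the read's best
   (lowest E-value) catalog HMM hit with E-value at most `e_max`
   (default 1e-5).
2. **Aligner consensus.** The read keeps that KO only if the
   KO-labelled hits among its best `k = 25` protein-aligner hits
   *unanimously* agree with the candidate, and at least one labelled
   hit exists.

Three choices here were genuinely open and are exposed as options:

- *Unanimity vs majority.* "The best 25 hits match" is read as
  unanimity of the KO-labelled subset (`rule = "unanimity"`); a
  majority variant exists but is not the default, because with a
  12-gene target catalog a single discordant label is strong evidence
  of a paralogous or promiscuous domain.
- *Unlabelled hits.* Aligner subjects without a KO label are ignored
  rather than treated as discordant (`strict_unlabeled = FALSE`):
  database coverage gaps should not veto an otherwise unanimous
  assignment.
- *Exact E-value ties* between catalog HMMs mapping to different KOs
  leave the read unassigned — with 64-bit E-values this is essentially
  a degenerate-input guard, and guessing between KOs would be worse
  than abstaining.

Genes supported by almost no reads are excluded before inference, the
way sparsely covered genes (a handful of reads sitting in single
replicates) must be: a gene is dropped when it has fewer than
`min_reads = 10` assigned reads in total or occurs in fewer than
`min_samples = 2` samples. The thresholds are parameters because the
underlying judgement ("a few reads, mostly in single replicates") is
qualitative.

## Abundance measures

Relative abundance of any feature (gene, family, family x gene pair)
is its read count divided by the *total bacterial reads* of the sample
— including reads unclassified at family level — times 100. Absolute
abundance is estimated by scaling with microbial biomass carbon:

    absolute = relative% * Cmic / 100   [mg biomass-C / kg soil]

This is a biomass-weighted proxy for gene quantity, not a copy number;
it inherits the assumptions of the chloroform fumigation-extraction
(CFE) method. CFE biomass itself is computed as the fumigation flush
divided by the extractability factor (kEC = 0.45 for C, kEN = 0.54 for
N). The division convention is the default because it reproduces
conventional Cmic magnitudes; a `k_mode = "multiply"` flag implements
the literal multiplicative reading for comparability.

Rarefaction curves use the exact hypergeometric expectation
E[S_n] = sum_g (1 - C(N - N_g, n)/C(N, n)), not resampling; the test
suite checks the formula against exhaustive subset enumeration and
Monte-Carlo subsampling.

The stable aggregate fraction (SAF) from wet sieving is
100 (retained - sand)/(initial * f - sand), with the sand + debris
mass measured after pyrophosphate dispersion; the moisture factor `f`
defaults to 1 (field-moist mass basis).

## Robust inference

All hypothesis tests are percentile-bootstrap tests on medians
(median as M-estimator, 2000 bootstrap resamples by default):

- **Two-group (per-trial tillage) test**: statistic
  `median(RT) - median(CT)`; groups resampled independently;
  `p* = (#{d* > 0} + 0.5 #{d* = 0}) / B`; two-sided
  `p = 2 min(p*, 1 - p*)`.
- **Two-way (trial x tillage) test**: observed statistics are sums of
  squared linear contrasts of the cell medians (row-margin, column-
  margin and double-centred interaction contrasts); the null
  distribution comes from centring every cell at its own median and
  resampling within cells; `p = #{T* >= T_obs}/B`.

These explicit algorithms are this package's reference behaviour for
the WRS-style `pb2gen`/`pbad2way` analyses; the exact internals of
those functions are not re-implemented from their source. The smallest
reportable p-value is `1/B`; raw bootstrap proportions are kept in
`p_raw`. BH false-discovery-rate control is applied across features
within one factor and dataset (per-trial tests: within trial by
default; a global variant is available since the original analysis
does not state the grouping). Soil covariates are not BH-adjusted.
Effect sizes are classical omega-squared from the ANOVA decomposition
(raw values retained, clipped at zero for reporting) and Pearson's r
from the pooled two-sample t statistic; whether a bootstrap analysis
should reuse the classical decomposition is itself unstated, so the
classical form is used and labelled as such.

**Granularity caveat.** With n = 3 replicate plots per cell the
bootstrap distribution of a median is supported on very few points.
Complete separation of two groups of three exchangeable continuous
values happens with probability 2/C(6,3) = 0.1 even under the null, so
the smallest p-values are reached far more often than their nominal
size suggests and BH inherits these anticonservative inputs. The
pipeline warns when group sizes are below 5, and recovery experiments
on synthetic data should be read as "superset-biased": planted effects
are found, along with occasional spurious features. Calibration is
checked at n = 20 per group (two-group) and 3 x 2 cells of n = 10
(two-way), sizes at which the percentile bootstrap is expected to be
near-nominal; at triplicate-plot sample sizes it is not, and no
correction is applied because the reference analysis applied none.
Under strongly skewed (lognormal) nulls the factorial test runs
conservative at any moderate cell size — the bootstrap of a centred
cell median overestimates the median's sampling dispersion by
10-20% there — so its realized size sits below, never above, the
nominal level.

## Ordination

Soil covariates are ordinated by PCA on the correlation matrix
(variables standardised; zero-variance columns dropped with a
warning). Community and gene-profile tables use Bray-Curtis
dissimilarity and principal coordinate analysis: Gower double-centring
of -D²/2, eigendecomposition, and — when negative eigenvalues beyond
1e-8 of the largest eigenvalue appear — the Cailliez additive
constant, obtained from the 2n x 2n companion eigenproblem and added
to all off-diagonal dissimilarities before re-decomposition. The
constant is reported (`correction_constant`, 0 when the configuration
was already Euclidean), all axes with eigenvalues above tolerance are
retained, and the corrected dissimilarities are reproduced exactly by
the full-dimensional embedding. PCoA is implemented in-package because
the analysis needs the constant and the corrected embedding as
first-class outputs; the `ape` implementation serves as an independent
cross-check in the test suite. The spelling "Cailliez" is used
throughout. Group ellipses around replicate triplets use the
chi-squared(2) quantile by default; with three points per group this
choice is material, so a Hotelling-type F-based quantile is available
(`quantile = "f"`).

Responder families are those whose gene-read abundance differs
between tillage treatments within a trial at BH-adjusted q <= 0.05.
Log2 fold changes are oriented RT over CT (recorded in the output
header) with a pseudocount of half the smallest nonzero table value —
scale-aware and standard. The cross-trial comparison is the exclusive
Venn partition of the per-trial responder sets.

## What the synthetic generator emulates

The generator reproduces the *structure* of the study — 3 trials x 2
tillage x 3 replicate plots, ~2.8 million bacterial reads per sample —
with everything downstream needs:

- **Gene reads.** A planted fraction (0.033% of bacterial reads by
  default) is split over the 12 genes in three abundance tiers
  (~0.0075% for *wza*/*lptF*/*lptG*, ~0.0015% for the moderate tier,
  below 0.001% for the rare tier), then over families proportional to
  the community composition. The multinomial draw is exact: gene reads
  plus decoy reads always equal the sample's read total.
- **Community composition.** Fourteen named dominant families (each
  above the 1% dominance threshold) plus a configurable rare tail
  (371 by default, for a 385-family inventory) whose shares decay
  geometrically from just below 1% to the ultra-rare range (the six
  rarest together ~0.0002% of reads); 35.8% of bacterial reads stay
  unclassified at family level. Per-trial compositions are Dirichlet
  draws over the dominant families, the aggregate tail mass and the
  unclassified fraction, with the within-tail profile held fixed — a
  per-family Dirichlet at any concentration that leaves dominants
  realistically variable would extinguish rare families, whereas in
  real data nearly every family occurs at every site. The
  concentration (default 2000, ~10% relative site variation for
  dominants) is a free parameter — per-family overdispersion is not
  reported anywhere to fit it to.
- **Planted effects.** Ledger rows give the RT:CT (or CT:RT) rate
  ratio for a gene or family in one trial; the two tillage cells are
  rescaled so their mean stays at baseline, which keeps the overall
  planted gene fraction fixed while making the realized count ratio
  equal the ledger value in expectation.
- **Detection model.** HMM E-values are log-uniform over [1e-12,
  1e-2], deliberately straddling the 1e-5 cutoff so the threshold is
  exercised on both sides; aligner top-25 lists agree unanimously with
  probability `p_agree = 0.9` and otherwise contain discordant KOs;
  4% of hits are unlabelled; decoy reads pick up spurious hit records
  at rate 1e-5. Under these defaults detection is lossy by design.
  The `detection = "calibrated"` configuration (E-values below the
  cutoff, `p_agree = 1`, no false hits) emulates hit tables that have
  already passed the upstream annotation pipeline's filters, which is the right
  comparison point for the printed summary numbers — the printed
  0.033% is itself a post-filter quantity.
- **Metadata.** Covariates are drawn per trial x tillage cell around
  the printed site means (e.g. Cmic 1341.9 / 342.2 / 121.5 mg/kg),
  with RT/CT offsets (+-10% for Cmic and Nmic, +-5% for Corg
  everywhere; +-8% SAF and +-3% pH only at the loamy site, creating
  the interaction) and 5% relative Gaussian noise (absolute 0.05 for
  pH). With zero noise the per-trial means equal the printed values
  exactly.
- **Reproducibility.** One master seed; the metadata stream, the
  composition draw and per-sample read streams are derived substreams,
  so outputs are byte-identical for identical inputs.

Deliberately *not* emulated: nucleotide sequences, quality scores,
real aligner score distributions, phylogenetic correlation between
families, and compositional coupling beyond the multinomial. Passing
tests therefore validate the pipeline's logic and statistical
behaviour under known truth — they do not certify recovery rates on
real soil metagenomes, where effect structure and overdispersion are
unknown.

A consequence of planting gene-level effects as trial-wide rate
ratios is that *every* family's gene reads shift in that trial, so
family-level responder counts in such configurations legitimately
exceed the planted family effects; family-recovery checks therefore
use configurations with family-only ledgers.

## Numerical choices and degenerate inputs

- Percentages are stored at full precision; rounding happens only in
  reports (one decimal for the summary percentages).
- Zero-total samples raise errors in normalisation; samples without
  any assigned gene read are excluded from the gene-profile PCoA
  (Bray-Curtis is undefined on an all-zero profile) but stay in every
  other table.
- Eigenvalue tolerances are relative (1e-8 of the largest);
  ellipse degeneracy uses a 1e-12 relative floor on the smaller
  covariance eigenvalue.
- The negative CFE flush is flagged, returned signed, never clipped.
- Single-trial designs skip the two-way tests (undefined) and keep
  the per-trial analyses.

## Problem sizes used in the checks

The packaged validation runs use scaled problem sizes chosen to probe
each property where it is informative: annotation equivalence on 1,000
random small fixtures; rarefaction enumeration at N <= 8 and
Monte-Carlo at N <= 200 with 10,000 draws; test calibration with 500
simulated null datasets at 500 bootstrap resamples; parameter recovery
with 100 replicates of a single-trial study at the full ~2.8-million
read depth; end-to-end runs at reduced depth (20,000-100,000 reads)
where only plumbing, not power, is under test.
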