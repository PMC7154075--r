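Package: epslps
Title: Targeted Metagenomic Profiling of Bacterial Exopolysaccharide and
    Lipopolysaccharide Biosynthesis Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for profiling the bacterial potential to
    produce soil-aggregating exopolysaccharides (EPS) and
    lipopolysaccharides (LPS) from shotgun-metagenome read annotations
    under two tillage intensities at multiple field sites. Reads are
    assigned to a 12-gene KEGG Orthology catalog by a consensus rule
    combining profile-HMM hits (E-value filtered) with agreement of the
    best 25 protein-aligner hits; gene and family abundances are
    expressed as percentages of bacterial reads and scaled to absolute
    abundances by chloroform-fumigation microbial biomass carbon (Cmic).
    Inference uses percentile-bootstrap robust two-way ANOVA and
    two-group tests on medians with Benjamini-Hochberg false discovery
    rate control and omega-squared / r effect sizes; ordination covers
    PCA of soil covariates and Bray-Curtis PCoA with Cailliez
    correction. A synthetic-data generator with planted site and tillage
    effects makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
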