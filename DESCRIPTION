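Package: gsevol
Title: Phylogenetic Analysis of Intron-Exon Gene Structure Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An orthology-free pipeline for studying the evolution of
    intron-exon gene architecture across species. Extracts per-gene and
    per-species gene-structure statistics (intron counts, intron and exon
    lengths, intron ratio, intronless fraction) from GFF3 genome
    annotations using canonical-transcript selection and CDS-span
    trimming; conditions dated phylogenies (recent-tip and short-branch
    collapsing); fits a rate-heterogeneous phylogenetic ridge regression
    yielding per-branch evolutionary rates and ancestral states, with a
    Brownian-motion baseline and rate-based tree rescaling; performs PGLS
    regression, AIC model comparison and simulation-based phylogenetic
    ANOVA; computes perturbation-based confidence intervals for ancestral
    states; interpolates trait trajectories on a time grid; and builds
    Kolmogorov-Smirnov distance matrices between whole-genome feature
    distributions with fixed-topology least-squares branch lengths and
    divergence-rate estimates. Includes a synthetic-data generator
    (annotated genomes, dated trees, Brownian traits with clade rate
    shifts) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
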