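---
title: "Modeling the evolution of intron-exon gene architecture with gsevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of intron-exon gene architecture with gsevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(gsevol)
```

# The problem

Eukaryotic genes differ enormously in how much of their length is intronic:
some lineages carry intron-dense genes with long introns, others have
streamlined, nearly intronless gene models. `gsevol` provides an
orthology-free way to study how this architecture evolves. Instead of
tracking individual intron positions across orthologs, it reduces each
genome to a handful of species-level statistics -- most centrally the
**intron ratio**, the total intron length divided by the total exon length
of a gene's canonical transcript -- and models those statistics as
continuous traits evolving along a dated phylogeny.

The pipeline has five stages:

1. **Feature extraction** from GFF3 annotations;
2. **Tree conditioning** of a dated phylogeny;
3. A **rate-heterogeneous trait model** (phylogenetic ridge regression)
   with a Brownian-motion baseline, ancestral reconstruction and
   perturbation-based confidence intervals;
4. **Comparative inference**: PGLS regression, AIC model comparison, and
   simulation-based phylogenetic ANOVA;
5. **Distribution-level divergence**: Kolmogorov-Smirnov distances between
   whole-genome feature distributions, turned into a divergence-rate tree.

A synthetic-data module generates annotated genomes, dated trees and
Brownian traits with known ground truth, so every stage can be validated
end to end.

# Feature extraction

Annotations are read from GFF3 (via `rtracklayer`). Because UTR annotation
quality is inconsistent across genome projects, all statistics are computed
on the **CDS span** of the **canonical transcript**:

* the canonical transcript of a gene is the one with the maximal summed CDS
  length (`select_canonical()`); ties are broken by the lexicographically
  smallest transcript id so results never depend on file order;
* exons are clipped to `[min CDS start, max CDS end]`
  (`trim_to_cds()`); exonic sequence wholly outside the span is discarded.
  Clipping (rather than dropping) partially overlapping terminal exons
  preserves their coding portion and keeps intron semantics consistent:
  every intron lies between two coding-flanked exon pieces;
* introns are the gaps between consecutive exons, with the 1-based
  inclusive convention `length = next_start - prev_end - 1`
  (`infer_introns()`); zero-length gaps are annotation artifacts and emit a
  warning instead of an intron.

Per-species summaries (`summarize_species()`) average over **all** genes,
counting intronless genes as intron ratio 0. The mean intron length is the
mean of the genome-wide pooled intron-length distribution, not a mean of
per-gene means, so large intron-rich genes weigh in proportionally.
`log10` transforms are applied to species-level length and ratio means --
never to the intron count -- because downstream trait models work best when
values do not span orders of magnitude. Genome size is the sum of
`##sequence-region` header lengths.

```{r extract-demo}
sim <- simulate_genome(genome_spec(n_genes = 300, species_id = "demo",
                                   utr_prob = 0.3, alt_transcript_prob = 0.2))
f <- tempfile(fileext = ".gff3")
write_genome(sim, f)
gs <- extract_gene_structures(f, "demo")
gs
```

# Tree conditioning

Dated trees (node ages in Myr before present) are read from Newick.
Two cleaning rules mirror common practice with large time-calibrated
phylogenies: species pairs that diverged less than 1 Myr ago carry
essentially no signal for Myr-scale trait models, so one member of each
such cherry is retained uniformly at random (`collapse_recent_tips()`,
applied iteratively so clusters of recent tips reduce to one
representative); and internal branches shorter than 1 Myr are collapsed
into polytomies (`collapse_short_internal()`). Both comparisons are strict
(`< 1`), and the ridge model handles polytomies natively, so no arbitrary
resolution is ever introduced.

Branches are attributed to named clades (phyla, kingdoms) by the rule that
a branch belongs to a clade when its **parent** node descends from (or is)
the clade's MRCA (`assign_branches()`); branches claimed by no clade are
`"stem"`. When nested clades both claim a branch the more nested (younger
MRCA) label wins.

# The rate-heterogeneous trait model

The core model (`rr_fit()`) is a phylogenetic ridge regression. Let
`X` be the root-to-tip path matrix: `X[i, b]` equals the length of branch
`b` if `b` lies on the path from the root to tip `i`, else 0. Tip values
are modeled as

```
y_i = a + sum_b X[i, b] * beta_b + e_i
```

so each branch carries its own signed rate `beta_b` (trait units per Myr),
and the state at any node is the root state plus the telescoping sum of
`beta_b * l_b` along its root path. With more branches than tips the
system is under-determined, hence the ridge penalty: `beta` minimizes
`||y - a - X beta||^2 + lambda ||beta||^2`.

Choices that matter:

* **Root state.** `a` is estimated first as the GLS phylogenetic mean
  under Brownian-motion covariance and then held fixed. This keeps the
  penalty from shrinking the root toward 0 and makes the `lambda -> 0` and
  `lambda -> Inf` limits interpretable (exact interpolation and a flat
  tree at the phylogenetic mean, respectively).
* **Penalty selection.** `lambda = "auto"` minimizes the leave-one-out
  cross-validated tip prediction error over a 40-point log-spaced grid
  from `1e-6` to `1e3`, using the closed-form LOOCV identity for ridge
  fits. The selection is a deterministic global search, and the chosen
  penalty is reported both raw and on the normalized scale
  `lambda / (1 + lambda)`.
* **Rescaling.** `rescale_tree()` replaces branch lengths with
  `|beta_b| * l_b`, renormalized so the total tree length is conserved
  exactly. A branch with fast change in either direction is a fast branch.
  Downstream BM-based methods run on the rescaled tree and thereby inherit
  the rate heterogeneity.

The single-rate Brownian baseline (`bm_fit()`) uses closed-form ML: the
GLS mean as the root, `sigma2 = r' C^-1 r / n`, and GLS conditional
expectations for ancestral states.

## Comparing the two models

Following standard practice for this family of models, the comparison is
made through PGLS: the same regression is fitted once with the original
dated tree (a pure BM error structure) and once with the rate-rescaled
tree, and the two AICs are compared (`compare_models()`). The rescaled
model "spends" its extra flexibility upstream, so a large AIC advantage
indicates genuine rate heterogeneity.

# Comparative inference

`pgls_fit()` implements generalized least squares with the BM covariance
`C[i, j]` = shared root-to-MRCA path length. Conventions: `sigma2` is the
ML estimate `RSS_gls / n` (used in the likelihood and AIC, with the
parameter count `k` = coefficients + 1 for `sigma2`); coefficient standard
errors use the unbiased `RSS_gls / (n - p)`; `R2` is measured against the
GLS intercept-only fit on the same covariance, and adjusted with the usual
`(n - 1) / (n - k - 1)` factor. ML (not REML) is used so AICs remain
comparable across fixed-effect structures.

`phylo_anova()` re-implements the simulation-based phylogenetic ANOVA: the
observed one-way F statistic is referred to a null distribution obtained
by simulating BM on the working tree with `sigma2` estimated from the data
by ML, with the add-one p-value `(1 + #(F_sim >= F_obs)) / (1 + n_sims)`
so finite simulation never yields p = 0. Running it on a rate-rescaled
tree gives the rate-heterogeneous version. Families of tests are corrected
with Benjamini-Hochberg FDR (`fdr_adjust()`).

# Ancestral states and their uncertainty

Point estimates of ancestral states come from the ridge fit. Uncertainty
from taxon sampling, topological error and dating error is quantified by a
perturbation protocol (`ancestral_ci()`): each replicate drops 20% of the
tips uniformly at random, swaps the tree positions of 10% of the remaining
tips (pairs constrained within the same phylum; trait values travel with
the tip label), and multiplies 10% of the internal node ages by
`U(0.5, 1.5)`, clamped so every parent stays older than its children. The
magnitude of the age perturbation is not prescribed by the protocol's
source; the multiplicative range is exposed in `perturbation_config()`.
Replicates are refitted until 100 valid ones are collected, a focal node
is matched in each replicate to the MRCA of its surviving descendants, and
the 2.5%/97.5% empirical quantiles (type-7) of the matched estimates form
the interval.

Two deliberate deviations from the source protocol:

* The original rejects replicates whose penalty factor falls below 0.9,
  a guard against local optima of its internal optimizer. Our penalty is
  selected by a deterministic global grid search with no local-optimum
  failure mode, and its scale is not comparable; the default here is
  therefore `lambda_min = 0` (no rejection), with the threshold exposed on
  the normalized `lambda / (1 + lambda)` scale for users who want the
  original behavior.
* Quantiles are taken over the raw replicate estimates (not over offsets
  from the full-data point estimate); consequently the interval need not
  contain the point estimate, and both are reported as-is.

**What these intervals are not.** All replicates re-use the one observed
dataset, so the interval measures robustness to sampling and dating
choices -- not the irreducible uncertainty of a deep ancestral state. For
the root in particular, the ridge estimate is by construction the GLS
phylogenetic mean of the tips, whose dispersion around the true (latent)
root state under BM is of order `sqrt(sigma2 / (1' C^-1 1))` -- several
times wider than the perturbation spread in our synthetic experiments.
Perturbation intervals for deep nodes should therefore be read as
stability diagnostics, and they undercover the simulated truth in the
package's own end-to-end validation (see the acceptance suite, where this
check is deliberately left failing rather than weakened).

# Time-sliced trajectories

Assuming a constant rate of change along each branch, the state at age `t`
on a branch with parent age `t0`, child age `t1` and endpoint states `v0`,
`v1` is `v(t) = m t + b` with `m = (v0 - v1) / (t0 - t1)` and
`b = v0 - m t0` (`branch_line()`). `clade_trajectory()` evaluates all
branches of each clade on a 5-Myr grid anchored at the present and reports
**both** the median and the mean across living branches -- descriptions of
this summary disagree between median and mean in the literature this
follows, so both are emitted and the choice is left to the analyst.

# Distribution-level divergence

Beyond species means, whole distributions diverge. For a chosen feature
(per-gene intron ratio or count, or the genome-wide pooled per-intron
lengths), `pairwise_ks_matrix()` computes two-sample Kolmogorov-Smirnov
distances `D in [0, 1]` between all species pairs (0 = identical,
1 = disjoint supports). `fit_branch_lengths()` then estimates branch
lengths in KS units on the **fixed** dated topology by ordinary least
squares over the pair-path incidence system -- the stated method is least
squares, so OLS is implemented directly rather than a minimum-evolution
criterion. The two root-incident branches of a bifurcating root are not
separately identifiable from tip-pair distances; they are merged for the
solve and the fitted length is split in proportion to their dated lengths.
Negative solutions are clamped to zero after the solve (a single pass;
an optional coordinate-descent NNLS refinement sits behind `nnls = TRUE`),
and residuals are recomputed after clamping. Dividing KS lengths by dated
lengths yields divergence rates (`divergence_rates()`): globally, per
clade, and per branch, in KS units per Myr (and x1000 per Byr).

# The synthetic-data generator

`simulate_genome()` emulates the inputs the pipeline consumes without
pretending to be a real genome: genes are placed without overlap, exon
counts follow a shifted Poisson (or are fixed), exon and intron lengths
are log-normal -- heavy-tailed like real intron-length distributions, with
an optional two-component mixture to mimic the distinct short/long intron
populations seen in some genomes -- and a configurable fraction of genes
is intronless. CDS equals the exons by default so that trimming is a
no-op and arithmetic oracles stay exact; UTR decoration (`utr_prob`) and
alternative shorter-CDS transcripts (`alt_transcript_prob`) exercise
trimming and canonical selection. The realized per-gene records are
returned as ground truth, so extraction can be checked for exact equality,
not just statistical agreement.

What it does **not** emulate: nucleotide sequence content, annotation
errors other than the injected ones, overlapping or nested genes,
trans-splicing, and intron gain/loss at specific positions. Passing tests
on these genomes therefore validate the pipeline's bookkeeping and
statistical machinery, not the biological realism of any particular
genome annotation.

`build_study_fixture()` assembles a full comparative study: a Yule tree
rescaled to a chosen depth, Brownian species-level traits (log10 intron
ratio, log10 intron length, intron count) with an optional rate-shifted
clade, and one genome per species whose generator parameters are tuned so
the expected extracted summary equals the simulated species mean (fixed
exon count `k + 1`, constant exon length solving
`ratio = k * mean_intron_len / ((k + 1) * exon_len)`, and log-normal
introns mean-matched via `meanlog = log(mean) - sdlog^2 / 2`). Extreme BM
draws can imply sub-1-bp exon lengths; the generator refuses them with an
error stating the constraint, and study-level callers redraw such rare
infeasible parameter combinations.

## Default study conditions

The end-to-end validation uses 16 species on a 500-Myr tree, 200 genes per
genome, a root intron ratio of 3, root mean intron length 500 bp, root
intron count 5, `sigma2 = 2e-4` per Myr for log10 intron ratio (about a
0.3 log10-unit root-to-tip sd -- comfortably within the spread observed
across eukaryote genomes), and a 5x rate multiplier in one root clade.
Statistical calibration runs use 64-100 tips and 100-500 replicates.
These sizes were chosen so each check exercises the estimator it targets
at meaningful power while the whole suite stays desk-scale.

# Known limitations

* Perturbation intervals are stability diagnostics, not calibrated CIs
  (see above); they undercover deep-node truth by construction.
* The ridge penalty scale is data-dependent; penalties selected by LOOCV
  are not comparable to penalties from other implementations of the same
  model family, and the normalized scale only partially mitigates this.
* OLS branch-length fitting weights all species pairs equally; distant
  pairs with saturated KS distances (near 1) can flatten deep branches.
* The extraction module trusts the annotation's exon/CDS coordinates;
  it detects and skips malformed parents but performs no further
  annotation quality control.
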