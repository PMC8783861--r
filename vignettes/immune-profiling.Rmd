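---
title: "Profiling the immune tumor microenvironment from nCounter panel counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the immune tumor microenvironment from nCounter panel counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoscape)
library(dplyr)
```

## The problem

Targeted expression panels such as the 770-gene immuno-oncology
CodeSets counted on the NanoString nCounter platform are a practical
way to profile the immune tumor microenvironment (TME) of routine
FFPE biopsies: they need little input RNA, tolerate fragmentation, and
cover marker genes for the major immune cell lineages alongside
checkpoint genes and cytokines.  `immunoscape` implements the full
analysis chain for such data — normalization, marker-gene immune cell
scoring, immunological-distance analyses, immune-hot/cold clustering,
and nonparametric differential statistics — together with a simulator
that generates nCounter-like cohorts with known ground truth, so every
stage of the pipeline can be validated without access to patient data.

The motivating design is a lung adenocarcinoma cohort of 114 tumors in
three genetic subgroups (31 ALK-positive, 40 EGFR-positive, 43
ALK/EGFR-negative), where the negative group is further split by
response to immune checkpoint blockade (16 long-term responders, 6
intermediate responders, 21 rapid progressors).  The simulator's
defaults reproduce exactly this design.

## Normalization model

Raw probe counts are transformed to log2 expression in four steps:

1. **Positive-control calibration.**  Each lane carries six synthetic
   positive controls spiked at a geometric ladder of known
   concentrations (128 down to 0.125 fM).  Per lane we regress
   positive-control counts on concentration through the origin; the
   fitted slope is the lane's detector sensitivity in counts per fM.
   Counts are divided by that slope (and multiplied by a fixed
   reference sensitivity, 30 counts/fM, purely to keep values on a
   familiar count-like scale).  Because every count in a lane — signal,
   background and spike-ins alike — shares the lane's scale, this
   calibration makes the normalized output *exactly* invariant to
   multiplying a lane's raw counts by any positive constant.  The QC
   report additionally shows conventional cohort-relative scale
   factors (geometric-mean slope over lane slope, renormalized to mean
   1) because those are what platform users are used to reading; they
   are reporting only and do not enter the expression values.
2. **Background flooring.**  Eight negative-control probes measure
   nonspecific binding.  Values are floored at the lane's mean + 2 sd
   of (calibrated) negative-control counts.  We floor rather than
   subtract so counts stay nonnegative and log-safe.
3. **Housekeeper scaling.**  Each profile is divided by the lane's
   median value over the housekeeping genes and multiplied by the
   cohort median of those medians.  Afterwards the per-sample
   housekeeper median is constant across samples (to 1e-9 in the
   tests).  Housekeepers are either the probes annotated as such, the
   packaged 20-gene list, or selected from a reference expression
   table: among genes with reference mean expression of at least 100
   (linear scale), the 20 with the lowest coefficient of variation
   (sd/mean, linear scale), ties broken lexicographically.
4. **log2 transform**, flooring at one count first so the transform is
   finite.

A lane whose positive-control slope is not positive fails QC and is
excluded with a warning; a zero housekeeper median is an error.

## Immune cell scores and derived readouts

The abundance score of each of 14 immune cell populations (B cells,
CD45+ cells, CD56dim NK cells, CD8+ T cells, cytotoxic cells,
dendritic cells, exhausted CD8+ T cells, macrophages, mast cells,
neutrophils, NK cells, T cells, Th1 cells, Treg cells) is the
arithmetic mean of the **log2** expression of its marker genes —
mean-of-logs, not log-of-mean, so adding δ to every marker's log2
value moves the score by exactly δ.  The packaged marker map follows
the Danaher et al. (2017) nCounter cell-score signatures and ships as
an editable TSV (`extdata/marker_map.tsv`); it is externally sourced
and deliberately easy to replace.  Markers absent from a matrix are
dropped from the mean with a warning; an empty population is an error.

Derived readouts:

* **Total TILs**: the unweighted mean of the population scores (all 14
  by default; configurable, since different signature versions use
  subsets).
* **Immunological distance**: the Manhattan (L1) distance between two
  samples' 14-dimensional score vectors, on raw (uncentered) log2
  scores.  The closeness test asks whether a query group (say, the
  ALK-positive tumors) sits nearer to one reference response group
  (LTR) than another (RP): per query sample it averages distances to
  each reference group and compares the paired means with a two-sided
  Wilcoxon signed-rank test.
* **PD-L1**: the CD274 row of the expression matrix, with a Spearman
  correlation panel against all population scores, overall and within
  subgroups.

## Hot/cold clustering

Samples are clustered on their score profiles with hierarchical
agglomeration: dissimilarity 1 − Pearson correlation, average linkage,
tree cut at k = 2.  The cluster with the higher mean total-TIL score
is labelled *hot*, the other *cold*.  Distances are computed on raw
scores; the per-population centering used for heatmap display (see
`autoplot()`) is display-only, because centering each population
changes between-sample correlations and we want the clustering to be
exactly reproducible from the score matrix.  Cluster labels are tested
against categorical annotations (genetic subgroup, fusion/mutation
variant) with Fisher's exact test, using the Freeman–Halton extension
beyond 2×2; two-sided p, no mid-p correction.

A constant sample profile has no defined correlation; such samples are
assigned distance 1 to everything, with a warning, rather than
aborting the run.

## Differential statistics

Both analysis levels — 14 population scores and all endogenous genes —
use the same engine: a Kruskal–Wallis omnibus test across groups
(tie-corrected H, chi-square approximation with groups − 1 degrees of
freedom), Benjamini–Hochberg adjustment of the omnibus p-values
*within each family* (the 14 populations, or all tested genes), and
for every pair of groups a two-sided Wilcoxon rank-sum test plus a
signed fold change.  The signed convention matches how fold changes
are usually quoted: with d the difference of group means on log2
scale, FC = 2^d for d ≥ 0 and −2^(−d) otherwise, so −2.1 reads
"2.1-fold lower" and the magnitude is always at least 1.  A contrast
is flagged significant when the omnibus q-value is below the FDR level
(5% by default) and the unadjusted post-hoc p is below 0.05; post-hoc
p-values are deliberately reported unadjusted, gated on the omnibus
family (a documented choice — the alternative of adjusting them too is
a one-line change on the output table).

Grouping modes: three-group (ALK / EGFR / NEG), four-group (ALK /
EGFR / LTR / RP, with the six intermediate responders excluded, as
response-stratified comparisons conventionally drop the ambiguous
middle), and covariate-stratified (the three-group analysis repeated
within smoking or TP53 strata; levels with fewer than two samples are
excluded with a warning).

The Wilcoxon implementation enumerates the exact distribution when
both groups have at most 20 observations and no ties, and otherwise
uses the normal approximation with tie and continuity corrections.
Gene-set analysis restricts a gene-level result to a set (e.g. the
cytokine–cytokine receptor panel genes), counts significant members
per contrast, and decomposes the two versus-NEG lists into
exclusive/shared parts.  The packaged 121-gene cytokine set is a
*synthetic stand-in* with the correct size and panel coverage (real
cytokine symbols plus `CYTSIM` fillers); substitute a curated pathway
list for real analyses.

## The synthetic cohort generator

The simulator is first-class, tested code; it emulates the features of
nCounter data the pipeline must survive, with known ground truth:

* **Counts** are negative binomial with per-gene baseline means
  (log-normal across genes; marker genes centered near 250 counts so
  log-scale effects are not floored away) and a shared dispersion
  (size 20 by default — moderate FFPE-like overdispersion).
* **Planted effects** are specified as signed fold-change contrasts on
  population scores (e.g. Treg ALK vs NEG = 2.1).  They are converted
  to per-(population, group) multipliers anchored at NEG = 1 and
  applied multiplicatively and identically to all of a population's
  marker genes, so the population score shifts by exactly log2(FC) in
  expectation and the truth is analytically checkable.  The packaged
  fixture plants the three headline contrasts (Treg 2.1 ALK/NEG, 1.9
  ALK/EGFR; cytotoxic −2.1 EGFR/NEG), which are mutually consistent.
* **Biological variability**: a latent per-sample log2-normal factor
  per population, sd 0.5 log2 units, shared by that population's
  markers — chosen once as a realistic bulk-tumor spread (about
  ±1 log2 at 2 sd) and exposed as `sigma_bio`, since real
  within-group variance is cohort-specific; plus independent per-gene
  noise (sd 0.4 log2 units).
* **Technical structure**: log-normal lane factors (sdlog 0.15),
  Poisson background with mean 5 counts added to every probe and the
  only signal on negative controls, positive controls proportional to
  concentration × lane factor with near-Poisson dispersion (size 2000:
  spike-ins carry no biological variance).
* **Covariates**: smoking status is drawn with subgroup-specific
  smoker probabilities (0.30 ALK, 0.40 EGFR, 0.95 NEG — driver-negative
  lung adenocarcinoma patients are overwhelmingly smokers), TP53
  status uniformly; both exist so the stratified analyses have
  realistic strata to work on.
* Intermediate responders are drawn from the same distribution as
  rapid progressors unless the effect specification addresses them
  explicitly, mirroring how such cohorts are usually analyzed
  (LTR vs RP).

What the simulator does **not** emulate: probe cross-hybridization,
FFPE degradation gradients, batch structure beyond lane factors,
tumor-purity variation, or correlated marker noise within a population
beyond the single latent factor.  Passing tests therefore demonstrate
algorithmic correctness and calibration under a well-specified
generative model, not robustness to every artifact of real FFPE data.

A reference-expression simulator produces a linear-scale table in
which the designated housekeepers have mean about 800 and CV about
0.02 while other genes vary several-fold, so the data-driven selection
rule provably recovers the packaged housekeeper list.

## Numerical and testing choices

* Normalization tolerances: housekeeper-median constancy is asserted
  to 1e-9; lane-scale invariance to 1e-12 (it is exact up to floating
  point).
* BH q-values are checked against a brute-force step-up oracle to
  1e-12 relative tolerance — the two mathematically identical
  formulas differ by one ulp of floating-point association.
* The Kruskal–Wallis p is validated against a 10^5-shuffle permutation
  oracle at three groups of 100: at that size the chi-square
  approximation error is far below the oracle's Monte-Carlo error, so
  "agreement within 3 Monte-Carlo standard errors" is a well-posed
  check.  At much smaller groups the approximation error itself
  dominates, which is a property of the chi-square approximation every
  standard implementation shares, not of this implementation.
* Exact Wilcoxon p-values are checked against full enumeration of all
  group assignments for combined sizes up to 12; Fisher 2×2 p against
  direct hypergeometric enumeration.
* Recovery and calibration runs use the study's group sizes
  (31/40/43) with 30 seeds for effect recovery and 50 seeds for null
  calibration — enough for the Monte-Carlo error of a mean fold
  change (about 0.03 on the FC scale) to sit well inside the
  tolerances being checked.
* Ties in CV-based housekeeper ranking break lexicographically; ranks
  in all rank tests use midranks with tie-corrected variances.

## Worked example

```{r example}
panel <- io_panel()
effects <- effect_spec(panel, contrasts = planted_effects(), seed = 1)
report <- run_pipeline(design = cohort_design(), panel = panel,
                       effects = effects, seed = 1, run_genes = FALSE)
report

glance(report)

report$recovery |>
  filter(abs(planted_fc) > 1) |>
  select(population, group_a, group_b, planted_fc, estimated_fc)

tidy(report) |>
  filter(significant) |>
  select(feature, group_a, group_b, fc, p_posthoc, q_omnibus)
```

The heatmap of centered scores in dendrogram order:

```{r heatmap, fig.width = 7, fig.height = 3.5}
autoplot(report)
```

## Limitations

* Marker-mean scores are relative abundances; they are not calibrated
  cell fractions and inherit every caveat of bulk deconvolution
  (shared transcripts across cell types, tumor-expressed markers).
* The default marker map and cytokine set are, respectively, an
  externally sourced signature file and a synthetic stand-in; both are
  meant to be replaced for production analyses.
* No batch correction beyond lane calibration is attempted, and no
  covariate-adjusted (regression) differential analysis is provided —
  the stratified reruns are the supported way to probe confounding.
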