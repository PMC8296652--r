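---
title: "Calling metastable epiallele status and its downstream associations"
author: "epistatus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling metastable epiallele status and its downstream associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistatus)
```

## The biological problem

A metastable epiallele is a locus whose epigenetic state is set
probabilistically around conception and is thereafter mitotically stable.
The motivating case is the nc886/VTRNA2-1 differentially methylated region
(DMR) on 5q31.1: the paternal allele is unmethylated in everyone, while the
maternal allele is methylated in roughly three quarters of individuals.  On
a methylation array this shows up as a *bimodal* beta-value distribution at
the DMR's CpGs, and individuals fall into discrete groups:

* **non-methylated** — neither allele methylated, median beta ≈ 0.10;
* **hemi-methylated** — one allele methylated, median beta ≈ 0.50;
* **intermediately methylated** — a minority (1–6%) whose cells are a
  stable mixture of hemi- and non-methylated states, median beta ≈ 0.35,
  distinguished as much by its irregular probe-to-probe profile as by its
  level;
* **fully methylated** — rare individuals with median beta above 0.60.

Because the state is categorical, stable for decades and set by the
periconceptional environment, it is a natural exposure for life-course
epidemiology: the package quantifies how the status drives the ncRNAs coded
in the region (and, through them, predicted target genes) and how it
associates with metabolic traits measured repeatedly from childhood.

## Pipeline overview

```{r pipeline, eval = FALSE}
coh  <- simulateCohort(cohortConfig(n_samples = 1000, seed = 1))
bm   <- betaMatrices(coh)[[1]]
region <- GenomicRanges::GRanges("chr5",
    IRanges::IRanges(135414000, 135417000))
bimodal <- detectBimodalCpgs(bm, region)
calls   <- callStatus(bm, bimodal$cpg[bimodal$bimodal])
stab    <- assessStability(calls,
    callStatus(betaMatrices(coh)[[2]], bimodal$cpg[bimodal$bimodal]))
fc      <- foldChangeByStatus(cohortExpression(coh)[[1]], calls)
```

## Identifying the informative CpGs

`scanCpgAssociations()` fits, per CpG, a linear model of an RNA level on
the CpG's beta plus covariates and flags genome-wide significant CpGs at
p < 5 × 10⁻⁸ — the conventional screen for expression-associated
methylation in a candidate region.  CpGs with constant beta are reported
with missing p-values and never flagged; rank-deficient covariate sets are
rejected rather than silently dropped.

`detectBimodalCpgs()` then requires, within a user-supplied region (BED
input is converted to the package's 1-based closed convention on read),
two things of a CpG before it is called bimodal:

1. **Hartigan's dip test** rejects unimodality at `alpha` (default 0.05).
   The dip statistic is implemented in the package from its definition —
   the smallest sup-norm distance between the empirical cdf and any
   unimodal cdf — via an exact reduction: for each candidate mode position
   the best convex fit below the upper ecdf corners and the best concave
   fit above the lower corners are found with incremental convex hulls,
   and the dip is half the best achievable worst gap.  Ties are handled
   exactly.  P-values come from Monte Carlo simulation of uniform samples
   (the asymptotically least favourable unimodal null); the null
   distribution depends only on n, so it is computed once and shared
   across CpGs of equal sample size (default B = 500, giving a p-value
   resolution of ~0.002 — ample for a 0.05 decision).
2. **Mode separation ≥ `min_separation`** (default 0.2 beta units), with
   modes estimated from a two-component Gaussian mixture.  This guard
   rejects statistically detectable but biologically trivial bimodality:
   allelic methylation differences are ~0.4 beta units, array noise an
   order of magnitude smaller.

## Calling status

`callStatus()` mirrors how such loci are analysed in practice:

* samples whose **median** beta over the bimodal CpGs exceeds
  `full_threshold` (default 0.60, strictly greater) are labelled `full`
  and excluded from clustering — they are qualitatively different (both
  alleles methylated) and too rare to cluster;
* the remaining samples are clustered on their bimodal-CpG beta vectors
  with `hclust` defaults — Euclidean distance, complete linkage — and the
  tree is cut at k = 3 (k = 2 when no intermediate group is expected);
* clusters are labelled `non`/`intermediate`/`hemi` by ascending cluster
  median beta, which guarantees the label-ordering invariant.

Missing betas are median-imputed per CpG when a sample is at most 50%
missing, otherwise the sample is dropped with a warning: imputation with
the column median is conservative here because the classification signal
is spread across all 14 CpGs.

The per-sample between-probe SD is reported (`probe_sd`) because the
intermediate group's profile variance is informative, but it is *not* used
for assignment — assignment stays a pure function of the beta vectors, so
the caller's behaviour is easy to reason about and to audit.

`assessStability()` compares two call sets over their sample intersection:
Spearman correlation of median betas, the fraction of identically-called
samples (concordance), and the identities of discordant samples, which are
the natural exclusion list for downstream analyses.

## Expression: ΔΔCq and fold changes

`normalizeDdcq()` converts qPCR Cq values to relative abundances,
2^(−(Cq(RNA) − Cq(ref))).  Undetected reactions must be encoded as
missing; they are *not* imputed at the assay's cycle ceiling, because a
ceiling imputation would manufacture fold-change signal for
low-expression groups (configurable by pre-processing the table if a user
prefers otherwise).

`foldChangeByStatus()` uses **medians**: each group's fold change is its
median abundance over the reference group's median (hemi-methylated by
default, so the reference group's FC is identically 1).  Group
comparisons use the Mann–Whitney U test (exact when both groups have ≤ 20
observations and there are no ties; otherwise the normal approximation
with continuity and tie corrections) and the Kruskal–Wallis test for the
trend when at least three adequately sized groups are present.  Rank
tests and median ratios make the analysis invariant to rescaling any
RNA's abundance — a property the test suite asserts.

## Correlated-target enrichment

The target analysis has two stages. `correlateTargets()` screens predicted
target mRNAs by Spearman correlation with the ncRNA, applying
Benjamini–Hochberg FDR over the tested targets only;
`selectCorrelatedTargets()` takes the genes at nominal p < 0.05 (strict
inequality; the union over several ncRNAs is supported).
`enrichGeneSets()` then tests each gene set by the hypergeometric upper
tail P(X ≥ k) with population N (the universe), K set members and n
selected genes, BH-adjusts across all sets, and reports sets with
q < 0.05 and overlap k ≥ 5.

Decisions at points the field leaves open:

* **Universe**: defaults to all genes appearing in at least one set of
  the supplied collection, the standard overlap-enrichment convention; a
  platform-specific universe can be supplied explicitly.  Overlap ratios
  k/K are universe-free and therefore the most portable numbers the
  module reports.
* **Overlap filter**: k ≥ 5 (configurable).  Published tables of this
  kind include k = 5 rows, so "more than five" phrasing is interpreted
  as ≥ 5.
* **k/K is reported rounded half away from zero** to 3 decimals (0.0625
  → 0.063), matching how such ratios are printed in publications; R's
  default round-half-even would print 0.062.
* Gene symbols are matched case-insensitively and deduplicated before
  counting.

## Lifecourse traits: windowed AUC estimates

For irregular repeated measurements, `traitAuc()` integrates the
piecewise-linear age–value curve over an age window (defaults 6–12, 6–18,
12–18, 18–24, 6–24 years) by the trapezoidal rule and reports the
**yearly estimate** = AUC / window width — the time-averaged trait level,
in the trait's own units.  This division convention is an explicit
modelling choice: it is the conventional reading of "estimate values per
age period", and it makes estimates comparable across windows of
different widths.

Boundary and coverage rules (both configurable):

* a measurement outside the window anchors linear interpolation at the
  boundary when it lies within 3 years of it; otherwise the window is
  truncated to the observed span and the AUC rescaled from the
  time-averaged level;
* an estimate requires ≥ 2 usable measurements spanning ≥ 50% of the
  window, else it is missing with a reason code (`insufficient_points`
  or `coverage`).

Skew-flagged traits are log-transformed before integration, so their
estimates are time-averaged log-levels.

`associateStatusTraits()` standardizes the estimate within the analysis
sample, excludes intermediately and fully methylated individuals (too few
for stable estimates), and regresses on the status indicator
(non-methylated = 1) plus covariates, reporting the effect in SD units
with a Wald 95% CI — repeated within sex strata on request.  When
follow-up windows are covered heterogeneously (samples recruited at
different ages), the baseline age should be among the covariates; the
synthetic cohort exports it for exactly this reason.

`testCategoricalAssociation()` cross-tabulates status against early-life
factors (maternal age group, income quartile, occupation class, ...) and
uses the classic *uncorrected* chi-squared statistic (Yates correction
available but off by default), overall and pairwise between factor
levels, with a low-expected-count flag when the asymptotic test is
doubtful.

## The synthetic cohort: what it does and does not emulate

`simulateCohort()` generates the joint structure every stage needs, from
one integer seed (all substreams derived from it; identical config + seed
gives a bit-identical cohort):

* **Status**: drawn per sample from configurable prevalences (defaults
  non 0.24 / intermediate 0.04 / hemi 0.715 / full 0.005, the binomial
  75/25 pattern plus the small exception groups), tilted multiplicatively
  within early-life covariate strata (younger and older mothers, lower
  income and occupational strata have more non-methylated offspring;
  parental education deliberately has no effect).  Tilt sizes give
  roughly 10-percentage-point prevalence differences.
* **Methylation**: 14 bimodal CpGs at state means 0.10/0.35/0.50/0.70
  plus flanking non-bimodal CpGs (mean 0.80) independent of status.
  Beta noise is truncated normal on the beta scale (clipped to [0, 1]) —
  simpler than a logit-normal and adequate for state separation.  Two
  stable per-individual components are essential and biologically
  motivated: a methylation *level* offset shared across CpGs and time
  points (`sample_level_sd = 0.015`), which is what makes median betas
  reproducible across decades within a status group; and, for the
  intermediate state, a per-CpG hemi-like cell fraction
  (mean 0.625 so the state mean is 0.35, SD
  `intermediate_profile_sd = 0.08`) drawn once per sample — the
  cell-mixture composition is established in early development and is
  mitotically stable, and this is what gives the group its
  characteristic irregular probe profile.  Per-measurement noise is
  `beta_sd = 0.008` per CpG.  These three scales were calibrated jointly,
  once, so that the generated population simultaneously shows >0.95
  longitudinal rank correlation of median betas, perfectly concordant
  status calls across time points at zero switch rate, and ≥95% truth
  recovery by the clusterer — the properties the analysis assumes of the
  real locus.
* **Expression**: lognormal abundances with status multipliers — fold
  change FC for non vs hemi (defaults 1.62 / 2.03 / 2.07 for the
  3p / 5p / 102nt species), √FC for intermediate (its RNA levels sit
  between the two main groups), 1/FC for full — with coefficient of
  variation `rna_cv = 0.5`.
* **Traits**: quadratic age trajectories plus additive status and sex
  effects in SD units (defaults: insulin +0.25 SD and glucose −0.20 SD
  for non vs hemi), measured at a childhood-cohort follow-up schedule
  (baseline age 3–18, re-examinations +3, +6, +9, +12, +21, +27, +31
  years).

Passing tests on this generator demonstrates parameter recovery under the
stated statistical structure — not performance on real arrays.  The
generator does not emulate probe-specific biases, batch or chip effects,
cell-type composition differences, genotype effects on expression, or
non-Gaussian beta error; conclusions about real data still require the
usual array QC and batch handling upstream of this package.

## Problem sizes and determinism

The test suite exercises the pipeline at the scales the methods are meant
for: status calling and stability at n = 300–1000 samples with 14 CpGs;
fold-change recovery at n = 2000 with a true 2-fold shift and CV 0.5;
type-I error checks over 1000 null regressions; the dip statistic
verified against exhaustively derived reference values and the
hypergeometric tail against full enumeration for all universes up to
N = 12.  `scripts/acceptance.R` re-runs the whole pipeline from scratch
at a user-supplied seed.  Every stochastic step takes an explicit seed;
Monte-Carlo nulls use a private RNG stream so they neither disturb nor
depend on the caller's RNG state.

## Known limitations

* The clusterer assumes one harmonized beta matrix; batches and arrays
  must be reconciled by the caller (cluster per batch, then compare).
* The dip test's Monte-Carlo null assumes complete observations per CpG;
  heavy, non-random missingness would distort it.
* The exact genomic extent of a DMR must be supplied by the user; the
  package does not discover region boundaries.
* The AUC yearly estimate is a time-average of a piecewise-linear
  interpolant; with very sparse measurements inside a window it degrades
  gracefully (missing with a reason code) but cannot recover trajectory
  shape.
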