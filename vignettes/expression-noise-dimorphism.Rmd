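---
title: "Detecting a sexual dimorphism in gene expression noise"
author: "noiseDimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a sexual dimorphism in gene expression noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiseDimorph)
```

## The question and the measurement model

Replicated expression data from inbred strains reared in a common
environment leave, within each strain and sex, only two sources of
variation among biological replicates: technical error and intrinsic
stochasticity of expression. The package quantifies that residual
variation per transcript and sex as the coefficient of variation (CV) of
the replicate abundances and asks whether the male CVs are systematically
larger (or smaller) than the paired female CVs across the transcriptome.

The CV uses the n−1 (unbiased-variance) standard deviation divided by the
replicate mean. With 3–9 replicates the denominator convention is
material; n−1 is the conventional default and is applied uniformly. CVs
are computed on the deposited linear-scale normalized values, with no log
transform; transcripts whose replicate mean is non-positive in either sex
(normalization can produce negative intensities) are excluded and counted,
since a CV with a non-positive mean is meaningless.

## The signed-rank statistic and its Monte Carlo null

For unit *i*, `d_i = CV_F,i − CV_M,i`. Ranks `1..n` are assigned by
ascending `|d_i|`; `W = Σ sign(d_i)·rank_i`. Two numerical choices matter
on real data and are fixed as follows:

* ties in `|d|` receive midranks (`rank(..., ties.method = "average")`);
* a zero difference keeps its rank with sign 0, contributing nothing —
  no unit is dropped, so `n` always equals the table size. Both cases
  have measure zero for continuous inputs.

The null is built by pooling all `2n` CV values, drawing a uniform random
permutation, refilling the n female and n male slots in order, and
recomputing W — the literal "rearranging all CV data" scheme rather than
per-pair sign flips. The two coincide in law for W: conditional on the
rank multiset, a global rearrangement makes each pair's sign an
independent fair coin, so `Var(W) = n(n+1)(2n+1)/6` for tie-free data.
This equivalence is itself a test in the suite (empirical variance within
5% of the closed form at n = 500, and an exhaustive-enumeration match over
all (2n)! refills at n ≤ 4), which is why the cheaper-to-state global
scheme was adopted without loss.

`P_upper`/`P_lower` count simulated W at or above / at or below the
observed value (ties on both sides, so they sum to ≥ 1); percentiles of
the null use linearly interpolated sample quantiles (`type = 7`), since
Monte Carlo noise dominates any quantile-method difference at 10,000
replicates. P-values are stored as exact fractions; only the report
renderers print a zero count as `<1/n_sim`. `n_sim` defaults to 10,000 and
every Monte Carlo entry point takes a mandatory seed and restores the
caller's RNG state.

## Mean–CV coupling per sex

`fitQuadratic()` is plain OLS of CV on `(1, mean, mean²)` with the
unadjusted R², on the raw scale — the simplest reading of the original
curve-fitting workflow; the coupling functions of the generator allow a
log-scale study if wanted. A constant response defines R² = 0 with a
warning rather than an error, because a flat CV profile is a legitimate
(if extreme) dataset. `r2SexRatio()` reports `R²_F / R²_M`; a male R² of
exactly zero yields `Inf` as an explicit flag rather than a number
pretending to precision.

## Chromatin-color stratification

Tracts come from a five-state segmentation of the genome (YELLOW, BLACK,
BLUE, RED, GREEN); a gene gets a color only when exactly one tract
contains its entire span. Internally the package uses `GRanges` (1-based
closed coordinates) and delegates BED/GFF3 conversion to `rtracklayer`;
containment is boundary-inclusive, and the semantics are identical to a
0-based half-open formulation. Two deliberate strictness choices:

* a gene crossing any tract boundary is unassigned, even when both
  neighbouring tracts share a color; a `mergeSameColor` option exists but
  is off by default, honouring the single-tract reading;
* unassigned genes never enter any stratum, nor the permutation pool.

The stratified test ranks within each color but draws, per Monte Carlo
replicate, a single global rearrangement of all colored CVs from which
every color's W is recomputed, so the per-color nulls share permutations
like the per-strain null they mimic. Within-color ranking is the only
scope consistent with per-stratum statistics: a stratum of n pairs must
satisfy `|W| ≤ n(n+1)/2`, and published per-color magnitudes sit inside
that bound for the stratum sizes, not under global ranks — the test suite
asserts the bound structurally.

## Dispersal analysis

Each species record carries a chromosome-system tag (XY, XO, ZW, ZO) from
which the heterogametic sex and W/Y presence are derived as total
functions. The observed statistic is the fraction of species whose
dispersing-most sex is the heterogametic one. The null permutes the
chromosome-system tags across the *full* table even when testing a W/Y
subset, with subset membership re-derived from the permuted tags: the
subsets are themselves tag-defined, so holding them fixed would condition
on the quantity being permuted. Records with unknown or unbiased dispersal
are excluded at load with a count.

The packaged 36-species table is a synthetic reconstruction (flagged in
its filename and documentation): the original species-level supplement is
not redistributed, so a table was rebuilt to satisfy every published
composition fact — 11/11/14 birds/insects/mammals, 5 species lacking W/Y,
observed heterogamety-biased fractions 0.81/0.90/0.20 — with the remaining
free choices (the XY/XO/ZW/ZO split and the number of male-dispersing
species) pinned by exact hypergeometric enumeration so that the
permutation null also reproduces the published percentile band. Species
names are plausible exemplars of each taxon, not the original list.

## The synthetic-data generators

`simulateExpression()` emulates a strain panel with three biological
replicates per strain and sex (the default: 6 strains × 2 sexes × 3
replicates, 1,000 transcripts). Per-transcript mean abundances are
log-normal (location `log(100)`, scale 1, arbitrary expression units);
female CVs are gamma(shape 4, scale 0.05), i.e. mean 0.2; male CVs are the
female CVs times the inflation factor γ (`noiseInflationGamma`).
Replicates are `mean × (1 + ε)`, `ε ~ N(0, cv²)` redrawn while
non-positive. No empirical effect size for γ exists, so the default of 1.5
is an arbitrary moderate dimorphism, documented as such; γ = 1 gives the
exact null used for type-I calibration. An optional pair of coupling
functions (`cvFemaleFun`, `cvMaleFun`) replaces the gamma draw with a
CV-versus-mean law for studying the R² machinery.

Two honest limitations. First, the zero-truncation compresses the realized
CV below the nominal one once `cv` approaches 0.5, so large `γ × cv`
combinations recover γ only approximately; parameter-recovery tests use
CVs small enough (≤ ~0.3) that the bias is negligible. Second, the
generator draws replicates independently with a common per-transcript CV —
it has no batch structure, probe-level artifacts, correlated technical
error, or sex-biased mean expression. Passing tests therefore demonstrate
the statistics' calibration and power under clean multiplicative noise,
not robustness to array artifacts.

`simulateTraits()` mirrors the three replication structures of strain-panel
stress assays: individuals per strain/sex/day analysed day by day
(startle-type), vial means as replicates (starvation-type), and means of
single-individual vial groups (chill-coma-type). The target sex CV applies
at the replicate level that the pairing procedure consumes (individuals in
the first design, group means in the others), with a small within-group CV
(default 0.05) underneath the averaged designs. `simulateDispersal()`
assigns tags from a stated composition and makes each species
heterogamety-biased with probability `pHetBiased`.

## Problem sizes and runtime choices

The suite sizes its simulations to run comfortably on one CPU: type-I
calibration uses 200 generator runs of 1,000 transcripts at 400
rearrangements each; power uses 100 runs of 2,000 transcripts at 9
replicates per sex; the closed-form null checks run 10,000 rearrangements
at n = 500, 4,907 and 16,637. The acceptance script reproduces the two
published null-percentile magnitudes at full size (10,000 × 16,637 and
10,000 × 4,907), about a minute and a half in total.

## Known limitations

* The Monte Carlo loop re-ranks per replicate in pure R; at 16,637 pairs a
  10,000-replicate null takes on the order of a minute. This is accepted
  in exchange for an implementation that is transparently the definition.
* The dispersal fixture is a reconstruction constrained by published
  marginals, not the original species list; species-level conclusions
  should not be read off it.
* The trait generator reproduces replication *structure*, not the
  empirical distributions of the original assays; the unequal pair counts
  of the published trait analyses arise from record-exclusion rules that
  are not fully specified and are not replicated here.
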