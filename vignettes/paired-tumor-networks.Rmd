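---
title: "Methods: differential connectivity and sCNV analysis in paired tumor cohorts"
author: "hccnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential connectivity and sCNV analysis in paired tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in hccnet, the
assumptions behind them, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices made where the methodology left room.

## The differential-connectivity meta-analysis

The core statistic treats the two tissues of a paired cohort as two strata
of a meta-analysis of one correlation coefficient. For a gene pair with
Spearman correlations $r_{AN}$ and $r_{TU}$, each is Fisher-Z transformed,
$z = \tfrac12 \log\frac{1+r}{1-r}$, with approximate variance $1/(n-3)$.
With weights $w_t = n_t - 3$ the heterogeneity statistic

$$Q = \sum_t w_t (z_t - \bar z)^2
    = \frac{w_1 w_2}{w_1 + w_2}(z_1 - z_2)^2$$

is $\chi^2_1$ under homogeneity. Assumptions: approximately continuous
margins (midranks absorb ties), independent samples within each tissue, and
$n > 3$ per tissue. Rank correlation makes $Q$ invariant to monotone
transformations of expression, which matters because tumor tissue often
shifts and rescales intensity distributions wholesale.

The retention cutoff $Q_0 = 80$ is the working default. Note that the
$\chi^2_1$ upper tail at 80 is $\approx 3.7\times10^{-19}$; a widely quoted
rounding of this cutoff to a p-value of $10^{-20}$ is not consistent with
the $\chi^2_1$ tail, and the package always reports the $\chi^2_1$ value.

Direction is decided by $|r_{AN}|$ versus $|r_{TU}|$, with ties (a
measure-zero event) credited to AN. A gene whose retained pairs are more
than 90% one-directional (strict inequality, so 9 of 10 is *mixed*) is a
gain-of-connectivity (GOC) or loss-of-connectivity (LOC) gene.

The scan is blocked: rank-standardized rows are multiplied blockwise
(`block_size`, default 1,000 genes), so memory stays bounded at a few
squared-block matrices regardless of gene count. The blocked scan is tested
for exact agreement with a per-pair brute-force oracle.

Two nulls accompany the scan. The *label permutation* swaps the AN/TU
assignment of each patient's two samples with probability one half and
rescans; FDR(t) is the mean permuted tail count over the real tail count.
One permutation is the default (each permutation costs a full scan and the
permuted counts at interesting thresholds are far from the real counts);
the count is configurable upward. The *split-half control* scans one tissue
against itself on disjoint random halves, which should retain essentially
nothing.

## Smoothed sCNV markers, cis/trans association and hotspots

LogR ratios are averaged over a 40-SNP window advancing by 20 SNPs within
each chromosome; a marker's position is the midpoint of its first and last
SNP. Smoothing assumes copy-number events are long relative to the window —
the whole-arm scale typical of tumor genomes — so averaging suppresses
probe noise without erasing events. Marker-level association is plain
Pearson correlation against covariate-adjusted expression; the default
retention cutoff is $|r| \ge 0.3$.

*Cis* is defined as the nearest marker within 5 Mb of the gene's single
anchor position (symmetric window; the map carries one position per gene;
equidistant markers resolve to the lower coordinate). *Trans* counting for
hotspots excludes genes on the marker's own chromosome by default, and the
default hotspot count uses signed $r > 0.3$, with an absolute-value option;
positive and negative trans counts are also tallied separately. Candidate
markers exceeding `min_genes` associated genes reduce to the top marker per
chromosome, because neighbouring windows covered by the same recurrent
segment are near-duplicates of one another.

The pairing permutation shuffles the marker matrix's sample labels as a
block: marker-marker and gene-gene correlation structures are untouched and
only the link between data types is destroyed, which is the correct null
for association counts.

## Stepwise variance decomposition

Per gene, forward selection over markers: the first candidate is the most
correlated marker genome-wide; each later candidate is the marker most
correlated with the current residual on a chromosome not yet in the model.
A candidate enters only if (a) its correlation p-value meets the entry
cutoff `entry_p = 5.1e-6` and (b) the residual-degrees-of-freedom RMSE
$\sqrt{SSE/(n-p-1)}$ strictly decreases. The reported quantity is the
adjusted $R^2$ of the final least-squares fit (0 for the empty model).

Two readings of the stopping rule were possible, and this is the package's
most consequential design decision. Applying the entry p-value only to the
first marker and accepting any RMSE decrease afterwards lets noise through
almost every step: the best of ~100 candidate markers nearly always has a
partial F above 1, so selection fills every chromosome and adjusted $R^2$
inflates far beyond the generating variance fraction. Requiring the entry
cutoff at every step matches the observed behaviour of such screens — the
vast majority of genes end with exactly one marker — and makes the median
recovered $R^2$ agree with the generating fraction within a few percent.
The package therefore applies the cutoff at every step. Collinear
candidates (rank-deficient fits) are refused with a log message.

## Survival screening

Each feature is standardized and fitted alone in a Cox proportional-hazards
model with Breslow handling of ties; the reported p is the Wald test.
Standardization makes coefficients comparable across features and leaves
p-values invariant to affine rescaling. Screening requires at least 10
events; constant features are flagged with p = 1. The FDR threshold is
empirical: survival records (time and event jointly, preserving the
censoring pattern) are permuted against samples `n_perm` times (default
100), FDR(t) is the mean permuted discovery count over the real count on
the grid of observed p-values, and the threshold is the largest grid point
with FDR at or below the target (0, flagged, when none qualifies — the
threshold is by construction monotone in the target).

## Enrichment

Over-representation uses the one-sided hypergeometric tail with fold
= observed / expected, expected $= |A||B|/U$; Bonferroni adjustment
multiplies by the number of tests (for module-by-term scans, the default
test count is modules × terms). Depletion is expressed through folds below
one rather than a left-tail p. The per-marker adjustment divides observed by
expected overlap per marker and pools by stratum,
$\text{ratio} = \sum\text{obs}/\sum\text{exp}$; since no aggregation rule
is canonical, significance is a documented choice: an exact binomial test
of the pooled observed count among pooled associated genes at success
probability $|T|/U$. The unique-term report ranks significant module-term
records per term and gives `diff` = top fold minus second-best significant
fold (= fold when the top module is the only significant one).

## Coexpression modules

Unsigned adjacency $a_{ij} = |r_{ij}|^\beta$ (Pearson here, by convention;
rank correlation is reserved for the differential scan). The unsigned form
is forced by fractional powers such as $\beta = 3.5$, which are undefined
for negative correlations. The scale-free fit index bins connectivity into
10 equal-width bins, drops empty bins (at least 5 occupied required), and
regresses $\log_{10} p(k)$ on $\log_{10} \bar k$; $\beta$ is the smallest
grid value (1 to 12 by 0.5) whose index reaches 0.7 *with a negative
slope* — a decaying degree distribution is part of the definition, and
requiring it prevents selecting an increasing fit. When no candidate
qualifies, the maximizer is returned with a flag.

A caveat found while validating: pure noise with few samples can produce
*high* fit indices at large $\beta$, because $|r|^\beta$ amplifies the
correlation extremes into an apparent heavy tail. A good fit index is
therefore necessary, not sufficient, evidence of network structure; the
package's tests exercise the flagged-fallback path on a degenerate
equicorrelated input instead of on small-sample noise.

Modules come from average-linkage clustering of TOM dissimilarity with a
static cut at an absolute height (default 0.95 on the 0-1 dissimilarity
scale). An absolute cut is used rather than a fraction of the dendrogram
height: for a single tight cluster the fractional rule cuts below every
merge and shatters the tree. Clusters below `min_size` (default 30) become
grey; labels are colors in descending size order. Dynamic tree cut and
module eigengenes are out of scope.

## The synthetic cohort generator

Defaults describe the study conditions the analysis expects: 200 matched
pairs and 2,000 genes on 8 chromosomes of 100 Mb with 300 SNPs each
(a ~16x downscaled genome that keeps marker, window and cis-distance
geometry realistic); Poisson(5) somatic segments per TU genome with
amplitude sd 0.5 logR and minimum length twice the smoothing window;
logR noise sd 0.1; expression noise sd 0.5 against unit factor loadings
(within-module correlation 0.8); cis slope 0.5 per sd of local dosage;
two hotspots carried by half the TU samples driving 100-gene regulons with
slope 0.5; five AN modules of 50 genes with half their loadings zeroed in
TU, three TU-only modules; per-gene age and sex coefficients of sd 0.1;
exponential survival with baseline median 36 months, hazard coefficient
0.7 per sd of summed survival-gene expression, and 30% censoring tuned by
an independent exponential censor. Regulon loadings are positive
(dosage-proportional activation), so the signed hotspot count sees the
whole regulon. All randomness flows from one seed through named substreams,
so adding a stage never perturbs earlier stages.

What the generator does *not* emulate: marginal intensity distributions of
real arrays, probe-level artifacts, clinical covariates beyond age and sex,
focal (sub-window) events, allele-specific copy number, and any
between-tissue communication. Consequently, passing recovery tests shows
the estimators are correct under the stated model, not that real cohorts
satisfy that model.

Two fields diverge from a literal reading of the configuration sketch the
package was planned against: the noise scale is split into `noise_sd`
(expression) and `logr_noise_sd` (logR), because a single scale cannot be
0.1 logR units and ~0.5 expression units at once; and the minimum segment
length is expressed in SNPs (`min_segment_snps = 80`).

## Problem sizes and numerical choices

The test suite and the acceptance script use: 50,000 independent pairs at
n = 150 for null-Q calibration; the default 2,000-gene cohort for
differential-pair recovery, stepwise recovery (cis slope set so the
dosage-explained fraction is 35%), hotspot detection (one implanted
hotspot, 150-gene regulon, `min_genes` 100 — the census cutoff scaled to
the simulator's gene count), and survival calibration/detection (100
survival permutations); 300 genes with two 100-gene blocks for module
recovery. These sizes make every stochastic check reproducible in seconds
to a couple of minutes while leaving comfortable margins around the
asserted bands.

Numerical details: correlations are clamped to $|r| \le 1 - 10^{-12}$
before the Z transform; $\chi^2$ tail p-values are floored at the smallest
positive double; robust fitting (MASS::rlm, bisquare, c = 4.685, at most 50
iterations) falls back to least-squares residuals with a flag on
non-convergence; age is standardized for conditioning and slopes are
reported on the original scale; covariates are adjusted separately per
tissue (the tissues are different states of the same patients, and pooling
would let tissue differences contaminate the covariate fit). Positions are
1-based internally; BED-like files on disk are 0-based half-open.

## Known limitations

Single permutations give coarse FDR estimates at thresholds where counts
are small; the Fisher-Z variance is asymptotic and slightly optimistic for
Spearman correlations at small n; the stepwise entry p is marginal (it
ignores selection over markers), which is conservative in effect because
the maximum-correlation candidate is tested against a fixed cutoff; and
hotspot detection reports at most one locus per chromosome, merging
genuinely distinct same-chromosome hotspots should they occur.
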