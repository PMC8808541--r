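---
title: "Discovering non-linear methylation-age trajectories with running medians"
author: "methylTrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering non-linear methylation-age trajectories with running medians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylTrend)
```

## The problem

Epigenetic clocks predict chronological age as a linear combination of CpG
methylation beta values, and most marker screens rank CpGs by their Pearson
correlation with age. Both presuppose that methylation changes linearly
across the lifespan. Many markers do not: some saturate at older ages, some
change abruptly around a particular age, some drift so slowly that a
perfect correlation corresponds to a biologically trivial change. A marker
gaining 0.0001 beta units per year from age 0 to 100 has correlation
essentially 1.0 with age yet changes only 1% in total; conversely a marker
that halves its methylation in a decade around age 60 may correlate poorly
with age overall and still be the biologically interesting one. Linear
screens keep the former and can lose the latter, and the saturating
markers they keep are exactly the ones that make linear clocks
underestimate age in old subjects.

methylTrend implements an alternative screen built on *running medians*:
assumption-free per-marker age trajectories from which markers are selected
by the magnitude of their change rather than the linearity of their trend.

## The procedure

**Quality control.** Beta values are used unnormalized. Probes on
user-supplied blacklists (SNP-overlapping, cross-reactive) are removed, as
are probes with more than `maxMissing = 10` missing values (strictly more;
a probe with exactly 10 is retained). Whole-sample outliers are detected by
mutual information: each sample's binned beta distribution is compared with
the cohort reference (the per-probe mean), and samples whose MI falls more
than `kSD = 3` standard deviations below the cohort mean are removed. Only
low MI flags a sample, and the pass runs once rather than iterating after
removals. The MI estimator is the plug-in estimator on a `bins × bins`
joint histogram of positionally paired values, with `bins = 10` equal-width
bins on [0, 1]; the bin count is exposed as a parameter because the
estimator is asymptotically insensitive to it in the regime that matters
here (tens of thousands of probes, relative comparison against the cohort
mean, units cancelling in the z-score).

**Age groups and running medians.** For every integer year from
floor(min age) to ceil(max age), the group holds the `k = ceil(0.1 n)`
samples nearest in age, so every year is estimated from the same number of
samples regardless of the cohort's age density. Distance ties are broken
by ascending sample index, making the grouping deterministic. At the edges
of the age range the nearest-sample rule drags group midpoints away from
the nominal year (a year represented by one young sample gets a group
reaching decades older); groups with |midpoint − year| > `tolerance`
(default 2 years) are trimmed, and the retained span is the analysis age
range. Within each retained group the per-marker median (less
outlier-sensitive than a mean; mean-of-middle-two for even counts) forms
the running-median track, together with the relative standard deviation
SD/median (n−1 denominator; +Inf where the median is 0) and the count of
non-missing values used. Missing values are excluded per marker-year, not
imputed.

**Selection.** Per marker, the maximum fold change
FC = max(median) / max(min(median), ε) with ε = 1e−6 guarding zero minima
(guarded markers carry an audit flag), and the maximum absolute change
Δ = max(median) − min(median); both are realised at the same pair of years.
A two-sided t-test (Welch by default; pooled variance available) compares
the raw beta values of the two extreme groups, Benjamini–Hochberg
adjustment is applied once across all QC-surviving markers, and the gates
are: FC selection `q < 0.05` and `FC > 2` (strict) and mean relative
SD ≤ 0.5; absolute selection `q < 0.05` and `Δ ≥ 0.2` (inclusive) and the
same spread gate; the overlap (joint) selection is their conjunction. The
mean relative SD averages over all retained intervals by default; a
`scope = "extremes"` switch averages only the two extreme intervals, since
"each interval used" admits either reading. Likewise the BH universe
defaults to all QC-surviving markers with a `spread_pass` switch. The
Pearson baseline (`pearsonSelection`) computes the raw beta-age
correlation, its t-transform p-value and BH q-values; zero-variance
markers are recorded as r = 0, p = 1 by convention.

Two caveats are inherited deliberately from the procedure itself. The
extreme groups of adjacent years can share up to 90% of their members, yet
the t-test treats them as independent samples. And the test conditions on
the groups being the *extremes* of the running-median track, which inflates
its significance under the null: in an all-null simulation roughly half of
flat markers reach q < 0.05 on the t-test alone, while essentially none
survive the full FC + spread selection. The q-value alone is therefore not
an FDR-calibrated quantity here; the selection's null control comes from
the conjunction of gates, which the test suite measures directly.

**Gradients and clustering.** Selected tracks are normalized by their own
maximum (so markers express relative change), differentiated by central
differences (one-sided at the ends, spacing from the actual retained-year
gaps), and clustered with k-means (`nstart` restarts, fixed seed). The
cluster count is chosen by the analyst; a t-SNE embedding of the gradients
plus a mean-silhouette scan over k = 1..6 provides an advisory suggestion
that is never applied silently. Clustering uses the raw normalized
gradients: the Savitzky–Golay filter (window 21, order 2 — each point
replaced by the centre value of a local degree-2 least-squares fit, edges
by polynomial extension, so degree-≤2 signals pass through exactly) is for
reporting and display, where the gradients' noise would otherwise obscure
the cluster shapes. No t-SNE implementation ships with this package's R
dependency stack, so `tsneEmbed` is an exact O(n²) t-SNE written here
(perplexity calibration by bisection, Student-t kernel, momentum descent
with early exaggeration), adequate for the post-selection marker counts
(tens to a few thousand curves).

**Overlap significance.** Whether a selection shares more markers with a
reference set (e.g. an epigenetic clock's CpGs) than chance allows is the
upper tail P(X ≥ x) for X ~ Hypergeometric(N, D, n). At array scale
(N ≈ 4·10⁵) the binomial coefficients overflow naive evaluation, so the
tail is computed term-wise in log-space (log-gamma binomials combined by
log-sum-exp). The normal approximation
Z = |x − 0.5 − np| / √(npq), p = D/N, with upper tail (1 − erf(Z/√2))/2,
is used when p − 2√(pq/n) > 0 and 10n < N; sparse overlaps fail the first
condition and take the exact branch. The tail probability is returned raw;
multiple-testing correction across several overlap tests is out of scope.
The universe N must always be supplied explicitly — the right universe
(pre- or post-filter probe count) is a scientific choice the tool refuses
to guess.

**Age prediction.** `rfCV` runs seed-shuffled 5-fold cross-validation
(train on 80%, validate on 20%) of a random-forest regressor on the
selected markers: 100 trees, all features per split, fully grown trees,
bootstrap resampling — the defaults of the toolkit the procedure was
designed around, all exposed. Missing features are imputed by the
training-fold marker median only. `linearCV` is the matched linear
counterpart (per-fold OLS on the same folds and imputation), standing in
for published linear clocks whose coefficient tables are not redistributed
here; `applyLinearClock` accepts any user-supplied coefficient TSV. Errors
are reported as mean absolute error per fold with SD across folds (the ±
is fold SD; median absolute error is available since published clocks
report it), plus per-fold Pearson r. `signedErrorByAge` computes the mean
signed error among samples at or above an age quantile (default 0.9):
negative values are the old-age underprediction signature.

## The synthetic cohort generator

Because the deposited cohorts are external downloads, every stage is
exercised on generated data with known ground truth. `simulateCohort`
draws ages uniformly or from a truncated-Gaussian mixture (dense middle
ages, sparse extremes — the shape of clinical cohorts) on a configurable
range, 0–102 years by default. `trajectorySpec`/`trajectoryEval` define
noiseless marker trajectories — constant, linear, logistic (saturating),
and step (e.g. an abrupt drop around age 60) — and `simulateBetaMatrix`
adds Gaussian noise, clips to [0, 1] (clip events are counted in the
truth object; additive-then-clip is simpler than beta-distributed noise
and adequate for rank-based statistics), punches missing entries at
recorded coordinates, and plants whole-sample outliers by permuting a
sample's values across probes — preserving the marginal distribution while
destroying probe-wise correspondence, which is precisely what the MI score
detects.

Study mixes are packaged as defaults: `studySpecs` (50 large planted
trajectories of amplitude 0.3 on baseline 0.1 with noise SD 0.03, split
across sigmoid/step/linear; 100 slow drifts of 1e−4 per year, the
1%-per-century family; flat markers for the remainder) and
`saturatingSpecs` (all markers logistic with midpoints 25–55 years and
rates 0.07–0.15 per year, so every trajectory plateaus before the oldest
ages — the regime where linear age models go biased). The generator does
not emulate Illumina chemistry, batch effects, probe-type differences,
cell-composition shifts or sex chromosomes; passing tests demonstrate that
the algorithms do what they claim on data with known truth, not that the
biological findings transfer to any particular tissue.

## Numerical choices and degenerate inputs

- Group size `ceil(fraction · n)`; tie-break by sample index; even-count
  medians as mean of the middle two.
- Relative SD +Inf at zero medians (marker then fails the spread gate);
  FC ε-guard 1e−6 with an audit flag.
- t-test degenerate groups (< 2 non-missing values) give a missing p and
  exclude the marker; two constant equal groups give p = 1.
- BH inputs outside [0, 1] are an error; missing p-values stay missing.
- Savitzky–Golay windows longer than the input shrink to the largest valid
  odd size, with a message.
- k-means and t-SNE are seeded; identical input and seed reproduce labels
  and embeddings exactly. Identical gradient curves fall back to a k = 1
  suggestion.
- Exact hypergeometric tails are clipped to [0, 1] against rounding at
  x = 0.
- Pipeline TSV artifacts store doubles with 17 significant digits so
  per-stage re-runs from artifacts are bit-identical with full runs.

## Problem sizes

The test suite and the bundled study configurations run at deliberately
modest sizes — cohorts of 150–400 samples and 30–1,000 markers, 10–20
simulation replicates per property — which keep a full check of every
stage in the low minutes on a single core while leaving all statistical
contrasts (planted-marker recovery, null behaviour, saturation bias)
clearly resolved. All sizes scale up through the same interfaces.

## Known limitations

- The extremes t-test inherits the selection bias and group-overlap
  caveats above; its q-values gate the selection but are not standalone
  FDR estimates.
- Running medians do not model covariates (BMI, cell composition); the
  procedure deliberately performs no normalization or adjustment.
- The t-SNE embedding is a diagnostic; distances in it are not calibrated
  and the advisory k is a silhouette heuristic.
- `linearCV` is an OLS stand-in for elastic-net-trained clocks; it shares
  their linear functional form, not their regularization.
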