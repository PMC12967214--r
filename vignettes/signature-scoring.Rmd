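---
title: "Scoring molecular signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring molecular signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tidysig)
```

## The problem

A molecular signature — a set of genes, proteins or metabolites whose
coordinated behavior marks a biological state — is only useful downstream
once its multi-feature profile is condensed into a single per-sample
number. Many summaries are in routine use (means, medians, enrichment
statistics, factor scores), they often disagree, and an observed score
alone says nothing about whether it could have arisen from a random set of
features or from noise in the data. tidysig computes a battery of summary
scores behind one uniform interface, lets each score compose with a data
transformation, and attaches resampling-based uncertainty to every
observed score.

Throughout, the input is a numeric feature × sample matrix `X` with
unique feature and sample identifiers, and a signature is an ordered set
of feature IDs with optional per-feature weights `w` (default 1; negative
weights encode "down" components of signed signatures).

## Scorers

Simple scorers reduce the signature's values within one sample `j`
(writing `v` for the non-missing signature values in that sample, and
`Q1, Q2, Q3` for quartiles):

* total quantity: `sum`, `weightedSum` = Σwᵢvᵢ;
* central tendency: `mean`, `weightedMean` = Σwᵢvᵢ/Σwᵢ, `trimmedMean`
  (drops ⌊g·n⌋ values per end, `trim` g = 0.1 by default), `median`,
  `mode`, `midrange` = (min+max)/2, `midhinge` = (Q1+Q3)/2,
  `trimean` = (Q1+2Q2+Q3)/4, `iqm` (mean of the central half of the
  sorted data);
* dispersion: `iqr` = Q3−Q1, `mad` (median absolute deviation from the
  median), `aad` (mean absolute deviation from the mean).

Matrix scorers use the signature submatrix across samples, or the full
feature background:

* `combinedZ`: feature-wise z-standardize, then score sample `j` as
  Σᵢ zᵢⱼ / √k for the k usable features. It follows that the `mean`
  scorer applied after the z-transform equals `combinedZ`/√k — a
  cross-module identity the test suite checks.
* `pca1`: sample coordinates on the first principal axis of the
  row-centered submatrix.
* `plage`: the first right singular vector (unit norm) of the
  row-standardized submatrix.
* `ssgsea`: a rank-weighted running-sum statistic per sample. All N
  matrix features are ranked by expression; walking the list from the
  top, the in-signature cumulative weight (rank^α, α = 0.25) minus the
  out-of-signature cumulative count is accumulated over all N positions.
* `gsva`: three stages — Gaussian-kernel cumulative statistics
  ẑᵢⱼ = (1/n) Σₖ Φ((xᵢⱼ−xᵢₖ)/hᵢ) with bandwidth hᵢ = sᵢ/4; per-sample
  descending ranks converted to the symmetric statistic t = |N/2 − r|;
  and a Kolmogorov–Smirnov-like walk whose enrichment score is the
  maximum positive plus the minimum negative deviation (τ = 1).

## Conventions the field leaves open

Several numerical conventions are not standardized across
implementations; tidysig fixes them once, documents them, and uses them
consistently in both the implementation and its test oracles:

* **Quartiles** are type-7 (linear interpolation), everywhere — scorers,
  confidence intervals and boxplot summaries.
* **trimmedMean vs iqm**: the trimmed mean drops whole observations
  (⌊g·n⌋ per end); the interquartile mean instead gives fractional
  end-weights when n is not divisible by 4, so it is continuous in n.
* **mode** on continuous data uses exact-value frequencies, ties going to
  the smallest value; since a continuous sample is usually all-distinct
  (making the mode the minimum, rarely meaningful) that case warns.
* **mad** omits the 1.4826 normal-consistency constant by default (it is
  a data summary here, not a robust σ estimate); `mad_constant = TRUE`
  restores it.
* **Sign of factor scores** (`pca1`, `plage`): singular vectors are
  sign-arbitrary, so scores are oriented to correlate non-negatively with
  the per-sample signature mean; an exactly-zero correlation leaves the
  sign as computed.
* **Ties in ranking scorers** (`ssgsea`, `gsva`) break by ascending
  feature-ID order, making every score fully deterministic.
* **Step transform** maps x to the number of thresholds ≤ x
  (left-closed intervals), an integer in 0..|thresholds|.
* **Quantile normalization** uses the classic per-rank cross-column mean
  as reference; ties within a column receive the mean of the reference
  values across their tied rank span (not the interpolated value at the
  average rank, which differs whenever the reference is locally
  non-linear).
* **z-standardization** is per feature with the n−1 standard deviation;
  zero-variance features become all zeros with a warning rather than NaN.

Transformations are applied to the **full matrix before signature
subsetting**, because the quantile and z statistics are only meaningful
against the complete feature background.

## Missing values and degenerate inputs

Simple scorers drop missing values per sample (`na_rm = TRUE`), reducing
the per-sample feature count `n_features_used`; a sample with no usable
values gets a missing score, never an error. `combinedZ` counts
zero-variance features as z = 0 (keeping the identity with the
z-transformed mean) and returns all-missing scores only when every
signature feature is constant. `pca1`, `plage` and `gsva` require a
complete submatrix and error on missing values — inside a
`sig_scores()` run such errors are downgraded to missing scores plus a
collected warning, so one bad signature never aborts the rest. `ssgsea`
drops missing values per sample, shrinking that sample's feature
universe. A zero-variance feature in `gsva` gets ẑ = 0.5 (the kernel CDF
of identical values) with a warning.

## Resampling nulls and inference

Whether an observed score reflects coordinated signal is judged against
empirical null distributions built by `build_null()` under two
complementary strategy families:

* **data resampling** (`data_with_replacement`,
  `data_without_replacement`): each sample column's values are resampled
  across features — i.i.d. draws or a uniform permutation. This destroys
  feature identity while preserving each sample's value distribution;
  it asks "is this score stable under/beyond the sample's own value
  spread?". The axis of resampling (within-column, across features) is a
  deliberate choice documented here: it keeps per-sample distributions
  intact, which is what the per-sample scorers condition on. Transforms
  are re-applied to every perturbed dataset so the null flows through
  exactly the same pipeline as the observed score.
* **random signatures** (`random_signatures`): B same-size feature sets
  drawn uniformly from all matrix features (overlap with the original
  signature permitted — the uniform null; `exclude_signature = TRUE`
  gives the competitive variant). This asks "does this feature set score
  higher than a random one?".

`compute_significance()` turns B replicates into an achieved significance
level, standard error, and confidence interval. The ASL uses the add-one
formulation, `(1 + #{replicates ≥ observed}) / (1 + B)`, so it is a valid
p-value and can never be 0 (its floor is 1/(B+1)); the two-sided version
doubles the smaller tail and caps at 1. The interval is the percentile
bootstrap interval (type-7 quantiles); BCa or studentized intervals would
be natural extensions but the percentile interval is the simplest one
consistent with standard bootstrap practice. **No multiple-testing
adjustment is applied** — the right correction depends on how many
signatures and scorers a study screens and is left to the analyst.

## Determinism and parallel execution

Every replicate draws its RNG seed from a counter-based derivation keyed
on (master seed, signature name, scorer id, replicate index), so results
are bit-identical whether the (signature × scorer) tasks run serially or
on forked workers, and regardless of worker count or scheduling. The test
suite asserts byte-identical output files between `--parallel` and
`--serial` CLI runs.

## The synthetic-data generator

`simulate_signature_data()` emulates the simplest situation in which a
signature score should work: i.i.d. normal (or log-normal) baseline
expression, a k-feature signature, and an additive shift δ applied to the
signature features in a known subset of "positive" samples. The shift is
applied on the sampling scale, so under the log-normal baseline it is
multiplicative on the data scale. `recovery_auc()` (the rank-sum AUC)
then measures how well any scorer separates positive from negative
samples.

What the generator deliberately does **not** simulate: within-signature
correlation, library-size or mean–variance structure of counts, batch
effects, or outlier samples. Passing recovery tests on these data
therefore demonstrates correctness of the scoring and inference
machinery under a clean mean-shift signal — not robustness to the full
complexity of real transcriptomes.

Reference problem sizes used by the checks (chosen as typical desk-scale
conditions): 200 features × 30 samples with k = 20 and δ = 1 for signal
recovery; B = 199 random-signature replicates for null calibration;
B = 999 with-replacement replicates of the mean of 50 N(0,1) values for
bootstrap coverage.

## A worked run

```{r example}
sim <- simulate_signature_data(100, 20, k = 10, n_positive = 10,
                               delta = 1, seed = 42)
run <- sig_scores(sim$matrix, sim$signature,
                  scorers = c("mean", "trimean", "ssgsea"),
                  strategy = "random_signatures", B = 99, seed = 42,
                  alternative = "greater")
tidy(run)
glance(run)
recovery_auc(run$scores$score[run$scores$scorer == "mean"],
             sim$labels$positive)
```

Tabular plot backings (and their `autoplot()` renderings) summarize a
run: `box_stats()` for score distributions, `scorer_correlation()` for
agreement between metrics (high agreement suggests the signature
summarizes robustly), `score_grid()` for the sample × scorer heatmap,
and `null_histogram()` for a null distribution with the observed score
overlaid.

```{r plots, fig.width = 6, fig.height = 3}
autoplot(box_stats(run$scores))
nulls1 <- dplyr::filter(run$nulls, sample_id == "s001", scorer == "mean")
obs1 <- dplyr::filter(run$scores, sample_id == "s001", scorer == "mean")
autoplot(null_histogram(nulls1$score, obs1$score, bins = 20))
```

## Known limitations

* Scores for very small signatures (k < 4) make several quartile-based
  summaries degenerate (they collapse to order statistics); the package
  computes them anyway and leaves interpretation to the user.
* The GSVA-style scorer implements the Gaussian-kernel variant only; a
  Poisson kernel for raw counts is out of scope.
* Identifier mapping between annotation systems is out of scope: feature
  IDs match by exact string equality, deliberately, to avoid silent
  aliasing.
* Sparse single-cell containers are not supported directly; densify the
  relevant submatrix first.
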