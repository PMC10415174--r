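---
title: "Models and methods behind lfqstats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lfqstats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: the
assumptions each method makes, the tunable parameters and their defaults, the
numerical choices taken where conventions diverge, and what the synthetic
benchmark can and cannot say about real data.

## The dataset model and provenance

All analysis runs on an `lfq_dataset`: a samples × proteins matrix of
(typically log2) intensities with `NA` for missing values, sample metadata
joined by exact name match, and an append-only log. Each preprocessing step
records its name, its complete parameter set including seeds, the matrix
shape afterwards, and a count of removed or imputed entries. Because every
step is a pure function of (matrix, parameters), `replay_log()` re-executes
the log from the stored raw snapshot and reproduces the current matrix
bit-for-bit; this is the reproducibility contract the whole package is built
around, and the test suite asserts it across randomly composed pipelines.

One semantics had to be fixed where conventions are silent: what "reset"
means after subsetting. Here `subset_samples()` re-bases the raw snapshot, so
`reset_preprocessing()` undoes normalization and imputation but *not* sample
selection. The alternative (resetting to the original import) silently
resurrects samples the analyst deliberately excluded, which we judged the
more dangerous surprise.

## Preprocessing

**Zeros.** Loaders keep `0` as written, because the import layer should be
lossless; `zero_to_missing()` makes the statistical decision explicit that an
LFQ zero is a failed quantification, not a measured abundance. It is required
before `log2_transform()`.

**Completeness filter.** A protein must be observed in at least
`ceiling(min_fraction × n_samples)` samples. The ceiling makes the gate
conservative at awkward fractions (0.6 of 4 samples means 3, not 2).

**Normalization** operates per sample on observed values only and never
reorders proteins:

* `median_center` shifts each sample's observed median to the grand median
  of sample medians (a location correction appropriate on the log scale).
* `quantile` replaces each sample's values by mean order statistics. With
  missing cells the textbook algorithm is undefined; here the reference
  distribution is built from proteins observed in every sample when any
  exist (otherwise from per-rank means over what is available), and each
  sample is mapped onto it by rank quantile with linear interpolation. Ties
  receive the mean of their ranks' reference values, so tied inputs stay
  tied. For complete data this reduces exactly to the standard algorithm.
* `zscore` centers and scales each sample (observed mean 0, sd 1); it
  refuses samples with fewer than two observed values.

**Imputation** fills every hole and never alters an observed cell — an
invariant the tests check for every method. The axis is per protein (across
samples), the field's convention, since proteins are the measured entities:

* `mean` / `median`: the per-protein statistic of the observed samples.
* `knn` (default `k = 3`): a missing cell takes the mean of that protein in
  the `k` nearest samples. Distances are Euclidean over the proteins
  observed in both samples, scaled by the number shared
  (`sqrt(sum((x−y)²)/n_shared)`), so sparsity does not mechanically shrink
  distances. Ties break by sample order; neighbours must have the target
  protein observed; a cell with no eligible neighbour falls back to the
  per-protein mean. These rules make the method exactly reproducible, and a
  brute-force nearest-neighbour oracle verifies them in the tests.
* `tree_iterative` (default 100 trees, `max_iter = 10`, relative-change
  tolerance `1e-3`): missForest-style chained prediction. Missing cells are
  initialised with per-protein means; proteins are visited in descending
  missingness order; each incomplete protein is regressed on all others with
  a random forest (`ranger`, single-threaded, seeded; `mtry = p/3`, the
  regression-forest default) and its missing cells are overwritten with the
  predictions; iteration stops at the cap or when the imputed cells stop
  moving. Random-forest imputation is the method repeatedly found strongest
  for LFQ data, because it can exploit the correlation structure between
  co-regulated proteins — see the benchmark caveat below.

## Differential expression

Tests analyse observed values only, gated by `min_obs` (default 2) per
group; there is no test-time imputation, keeping testing and imputation
orthogonal. Proteins whose statistic is undefined — too few observations, or
zero variance in both groups — are reported as `skipped_low_n` with an
undefined p rather than rescued with an epsilon, because epsilon choices
silently alter rankings. Benjamini–Hochberg q-values are computed over the
*tested* proteins only; including skipped ones would deflate q arbitrarily.

The t-test is Welch by default (per-protein variances are rarely equal
across conditions); `equal_var = TRUE` gives the pooled test, whose square is
the two-group ANOVA F (asserted to 1e-9 in the tests). ANOVA uses the classic
equal-variance F; ANCOVA fits least squares on group indicators plus numeric
covariates and takes the partial F against the covariate-only model, skipping
proteins with rank-deficient observed designs (e.g. collinear covariates).
Note the partial F has one fewer residual degree of freedom than the plain
ANOVA F, so even a perfectly uninformative covariate shifts p slightly — the
tests pin down the exact df relationship rather than pretending equality.

Over-representation analysis is offline by design: a user-supplied term →
protein mapping (two-column TSV or GAF-like file), hypergeometric upper-tail
p per term restricted to the background, BH across tested terms. No ontology
is bundled and no web service is called, which keeps the feature testable
against exhaustive enumeration.

## SAM

The permutation test follows the canonical two-class unpaired form. Per
protein, `d = (x̄₁ − x̄₂)/(s + s₀)` with `s` the pooled standard error. The
fudge factor `s₀` exists because low-`s` proteins otherwise dominate the
ranking; `auto` mode evaluates the 0th, 5th, …, 100th percentiles of the `s`
distribution and picks the candidate minimizing the coefficient of variation
of `mad(d)` across windows of `s` quantiles (up to 10 windows of at least ~5
proteins; with fewer than ~2 windows' worth of proteins the median of `s` is
used). Ties take the smallest candidate.

The null comes from relabelling samples: all `choose(n, n₁)` assignments are
enumerated when that number is at most `n_perm` (e.g. 20 splits for 3 vs 3),
otherwise `n_perm` assignments are drawn uniformly under the seed. Expected
order statistics `d̄₍ᵢ₎` are per-rank means of the sorted permuted scores.

**Calling** uses Tusher's outward scan: from the origin of the expected
scores moving up, the first rank with `d₍ᵢ₎ − d̄₍ᵢ₎ ≥ Δ` sets the upper cut
and everything above it is called (symmetrically downwards). A plainer rule —
call wherever `|d₍ᵢ₎ − d̄₍ᵢ₎| ≥ Δ` — looks equivalent but is not: in the
all-null limit the observed `d` hug zero while `d̄₍ᵢ₎` spread like a null
quantile line, so the plain rule "calls" proteins precisely because they are
*less* extreme than expected. The outward scan calls nothing there, which is
the behaviour a false-discovery procedure must have.

**FDR** at `Δ` is `π₀ × median_b(#{permuted d outside the cuts}) / n_called`,
capped at 1 and defined as 0 when nothing is called; the median (rather than
mean) false-call count is the original convention and is isolated in one
function should a user want the mean. `π₀ = min(1, fraction of observed d
inside the permutation null's 25th–75th band / 0.5)`. Per-protein permutation
p-values use the +1 correction, `(1 + #{|d_perm| ≥ |d|})/(1 + B)`, so they
are valid (never zero). The delta table tabulates every distinct deviation,
so calls are piecewise constant between rows; an independent exhaustive
oracle reproduces the whole table on 3v3 and 4v4 designs in the tests.

**Missing data.** Proteins with fewer than two observed values per group are
excluded up front. The remaining submatrix must be complete (the error
directs to imputation): with per-protein varying group sizes under
permutation, the order statistics across proteins are no longer comparable
and the exhaustive null loses its meaning. Running SAM after imputation is
the supported path.

If no `Δ` is given, the smallest tabulated `Δ` with FDR ≤ 0.05 (and at least
one call) is chosen and recorded in the result.

## Multivariate views and figures

PCA is column-centered, unscaled `prcomp` on the complete matrix with a
deterministic sign convention (each component's largest-magnitude loading is
positive), so scores are reproducible across runs and platforms. Hierarchical
clustering wraps `hclust` with Euclidean or correlation (1 − Pearson r)
distance and single/complete/average linkage; constant rows are rejected
under the correlation metric rather than producing NaN distances.

Figures come in two forms: `autoplot()` ggplots for interactive work, and a
deterministic SVG 1.1 writer for pipelines. The SVG emitter uses fixed
element order, fixed 3-decimal coordinate formatting and no timestamps, so
equal inputs and style give byte-identical files — which is what makes
end-to-end reproducibility testable at the byte level. Volcano y-values use
raw p by default (adjusted p optional); p = 0 is clamped to the smallest
positive double and flagged rather than becoming infinite.

## The spike-in benchmark

`generate_spikein()` simulates the standard two-group spike-in design on the
log2 scale: per-protein base abundances uniform on `protein_mean_range`
(default 14–26 log2 units, the usual LFQ dynamic range), a `log2_effect`
shift for spiked proteins in group B, i.i.d. Gaussian noise (default sd 0.3
log2 units, a typical replicate CV), then missingness — MCAR first, then
MNAR: cells whose noise-free intensity lies below the `mnar_quantile`
(default 0.25) of all noise-free values drop out with probability
`mnar_prob`, emulating detection-limit censoring. Everything is seeded;
equal designs give identical data.

What the simulator deliberately does **not** contain: correlation between
background proteins (no co-regulation, no sample loading factors), peptide-
level effects, batch structure, or heavy-tailed noise. That limits what the
benchmark can show. In particular, random-forest imputation earns its
reputation on real data largely by exploiting inter-protein correlation;
here the only exploitable structure is the mutual correlation of the spiked
proteins through the group effect. Consequently the tree-vs-mean AUC gap on
this generator is real but small (≈0.001–0.005, tree ahead in 8 of 10
seeds), smaller than single-realisation noise. The acceptance test and
script therefore compare the two methods as means over five replicate
generator seeds — the quantity the direction claim is actually about — and
they verify separately that with no missingness and low noise the pipeline
reaches AUC 1.0. Passing these tests demonstrates correct machinery and the
expected direction under censoring; it does not quantify the (larger)
advantage tree imputation shows on correlated real spike-in data.

AUC itself is the rank-based (Mann–Whitney) form: the probability that a
random spiked protein outscores a random background protein, ties counting
one half, skipped proteins at the minimum score. It is invariant to monotone
transforms of the score; the default score is −log10 of the raw t-test p.

## Problem sizes and budgets

The test suite runs its simulations at deliberately modest sizes — 500
proteins for null-calibration and power checks, 3v3/4v4 designs for
exhaustive permutation oracles, 16 samples per group for the SAM power
property (the size at which a 2-pooled-SD shift separates cleanly from the
maximum of 480 null scores; at 5 per group that property is statistically
unattainable, which is a fact about the design, not the method). The
acceptance script uses 500-protein designs with 5 replicate seeds.

## Known limitations

Two-class unpaired SAM only (no paired or multi-class variants); no
moderated/empirical-Bayes t-statistics; no batch-effect correction or
variance-stabilizing transforms beyond log2; no peptide/PSM-level import or
isobaric labelling channels; ORA requires a user-supplied annotation. The
dialect definitions pin common column conventions of each search engine;
exotic export configurations may need the generic loader.
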