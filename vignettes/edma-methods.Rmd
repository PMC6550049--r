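---
title: "Landmark-based form comparison with edmorph: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based form comparison with edmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmorph)
```

## The problem and the representation

Comparing the 3D anatomy of two groups of specimens — say mutant mice and
their unaffected littermates — from landmark coordinates runs into an
immediate nuisance: coordinates live in an arbitrary frame. Euclidean
distance matrix analysis (EDMA) sidesteps superimposition entirely by
rewriting each configuration of $K$ landmarks as its **form matrix** (FM),
the vector of all $K(K-1)/2$ unique inter-landmark distances. Distances are
invariant to translation, rotation, and reflection, so two forms can be
compared without choosing an alignment, and reflection invariance is what
lets a right hemimandible be compared to a left one directly.

The observational model is the classical perturbation model: each specimen
is a true group mean form plus independent random displacement at every
landmark. `simulate_group()` generates data under exactly this model
(isotropic Gaussian noise per coordinate, optionally heteroscedastic per
landmark), which is what makes the whole pipeline testable against known
truth.

## Mean forms

`estimate_mean_form()` supports two estimators:

* **arithmetic** (default): the per-pair mean of observed distances.
  Simple and robust, but biased upward under coordinate noise: for a true
  distance $\delta$ and isotropic noise $\sigma$ per coordinate on each of
  two landmarks, $E[d^2] = \delta^2 + 6\sigma^2$ in 3D, so
  $E[d] \approx \sqrt{\delta^2 + 4\sigma^2} > \delta$.
* **moment**: per pair, $\sqrt{\max(\overline{d^2} - \widehat{var}(d),
  \epsilon)}$. Because $\overline{d^2} - \widehat{var}(d) =
  \bar d^2 - \widehat{var}_{pop}(d)/(n-1)$, this is a variance-based
  shrinkage that always sits at or below the arithmetic mean; it is an
  approximation, not a full noise deconvolution (which would require
  subtracting the entire $6\sigma^2$ term and estimating $\sigma$ from the
  coordinate level). Where the correction would be non-positive the
  estimator falls back to the arithmetic mean and records the pair in
  `fallback`; with strictly positive distances this cannot actually occur
  (the corrected value equals $\sum_{i \ne j} d_i d_j / (n(n-1))$), so the
  branch exists for defensive completeness. The Monte-Carlo bias property
  (absolute bias strictly below the arithmetic estimator's at
  $\delta = 4$ mm, $\sigma = 0.2$ mm, $n = 2000$) is what the test suite
  asserts; no claim is made of replicating any particular legacy
  implementation.

The arithmetic estimator is the default because "average form matrix" is
the plainest reading of the procedure and the moment correction is small
at realistic noise levels (at 1–2% coordinate noise the two differ in the
fourth decimal).

## Form differences and effect bands

`compute_fdm()` forms the **form-difference matrix** (FDM): per-pair
ratios of like distances, test group over reference group, so a ratio
above 1 means "larger in the test group". The orientation is recorded in
the result; swapping groups inverts every ratio.

`classify_fdm_effects()` reproduces the distance-map reading of results:
only distances whose bootstrap interval excludes 1 get a direction band —
5–10% or >10%, increase or decrease — from the *point-estimate* ratio;
significant distances below the 5% band are reported as
`significant_lt5`. Significance (interval-based) and magnitude
(point-estimate-based) are deliberately separated, because conflating them
makes the 5% criterion ambiguous. Decrease thresholds are multiplicative
($r \le 1/1.05$, $r \le 1/1.10$) since ratios compose multiplicatively;
an additive variant ($r \le 0.95$, $0.90$) is available behind the
`decrease` argument.

## Bootstrap inference

Two resampling schemes, both non-parametric on specimens and both driven
by a single integer seed with a fixed draw order (group A's indices, then
group B's, each iteration), so identical inputs and seed give bit-identical
output on any platform:

* **Confidence intervals** (`bootstrap_fdm_intervals()`): resample
  specimens with replacement independently within each group at the
  observed sizes, re-estimate both mean forms, recompute all ratios; take
  marginal two-sided percentile intervals. Percentile intervals (no BCa)
  keep the procedure transparent and exactly checkable against a
  brute-force reimplementation of the loop, which the test suite does
  bit-for-bit at small resample counts. The default level is 0.90; the
  reference analysis protocol fixes the resample count (100,000) but not
  the level, so the level is an explicit, recorded parameter.
* **Mean-form equality test** (`test_mean_form_difference()`): the
  statistic is $T = \max_{ij} FDM_{ij} / \min_{ij} FDM_{ij}$, the spread of
  the ratios. The null distribution pools all specimens and draws both
  pseudo-groups with replacement from the pool — the standard
  nonparametric construction of "the mean forms are the same". The
  p-value is the add-one estimator $(1 + \#\{T^* \ge T_{obs}\})/(1 + B)$,
  so it is never exactly zero and its floor $1/(1+B)$ is visible in the
  output.

Two properties of $T$ worth knowing: it is at least 1 by construction, and
it measures ratio *spread*, so it is blind to a pure size difference (a
uniformly scaled copy has all ratios equal and $T \approx 1$). Size-only
effects show up in the confidence intervals (every interval excluding 1)
and in the form-mode PCA, not in the test. No multiplicity correction is
applied across pairs: the procedure is interval-based per distance, and
the per-distance false-positive rate is the complement of the interval
level. At group sizes around 25 the percentile intervals are mildly
anti-conservative, so the realized per-distance exclusion rate under the
null sits slightly above the nominal 10% at the 0.90 level — visible in
the validation simulations and worth remembering when reading
significant-distance counts.

## PCA of ln-distances

`ln_distance_table()` + `run_pca()` implement ordination in distance
space: natural log of every inter-landmark distance, then
eigendecomposition of the column variance-covariance matrix (covariance,
not correlation — distances share units and their relative variances are
meaningful). Two modes, both exposed because form ("size and shape
together") and scale-free shape are both legitimate questions: with
`scale_free = TRUE` each specimen's distances are geometric-mean scaled
first, which in log space is row-centering. For shape analyses,
geometric-mean scaling (rather than centroid size) keeps everything inside
distance space and makes the scale-free FDM of a pure scaling contrast
exactly 1.

Numerical choices: when pairs outnumber specimens the decomposition runs
through the specimen-space inner-product matrix (identical non-zero
spectrum, verified against the direct route in the tests); each component
is oriented so its largest-magnitude loading is positive, a deterministic
sign convention so scores are stable across platforms; explained fractions
are relative to the total variance (trace), not the retained components.
`group_separation()` summarizes separation as the ratio of centroid
distance to pooled per-dimension within-group dispersion, which makes the
value comparable across subspace dimensions.

## Replicate digitization and QC

Landmarks digitized twice per specimen are averaged per axis
(`average_digitization_trials()`), which halves the placement-error
variance. Every landmark's Euclidean inter-trial displacement is reported,
and placements exceeding the acceptance threshold (default 0.05 mm) are
flagged — *advisory* flagging: the flagged landmark is still averaged,
because the upstream protocol does not prescribe exclusion and silently
dropping data is worse than reporting it. Missing landmarks are a hard
error throughout; imputation is out of scope.

## The synthetic-data generator

`make_template_form()`, `apply_regional_effect()`, `simulate_group()`, and
`simulate_digitization_pair()` generate the validation conditions: a
16-landmark template in a 10 × 4 × 3 mm envelope (split into an 8-landmark
anterior body and an 8-landmark ramus region), two groups of 25 specimens,
coordinate noise of 1% of the mean inter-landmark distance, localized
effects as radial expansion of a landmark subset about its own centroid
(so within-subset distances scale exactly by $1 + m$ and unaffected-only
distances are untouched — exact ground truth for localization tests), and
replicate digitization noise at or below the 0.05 mm acceptance threshold.
Group sizes and noise echo realistic newborn-mouse cross-sectional studies
(20–40 per group, sub-0.1 mm landmark error on a ~1 cm structure).

What the generator does *not* emulate: anatomically realistic mandible
geometry, correlated (non-isotropic) landmark noise, allometry, or
outliers. Passing tests therefore certify the statistical machinery under
the perturbation model, not robustness to every property of real µCT
data.

Validation problem sizes used by the test suite: 200 replicate null
studies and 50 replicate effect studies at $n = 25$/group with 500
bootstrap resamples each, oracle bit-identity checks at 50 resamples, and
Monte-Carlo estimator checks at $n = 2000$. These sizes give stable
operating-characteristic estimates (99% binomial envelopes are used for
rate assertions) while keeping the default test run fast.

## Workflow and reproducibility

`run_full_analysis()` chains subsetting, the test, the intervals, the
classification, and the PCA over the whole landmark set plus named
regional subsets; `run_asymmetry_analysis()` does the same for left
versus right sides after `match_bilateral()` relabels right-side
landmarks onto their left homologs. Unit $k$ uses seed
$\mathrm{seed} + k - 1$, all inputs are validated before computation, and
outputs (per-unit FDM tables as CSV, the report as JSON) are written only
after every unit succeeds. Rerunning a config with the same seed
reproduces every number bit-identically; the report records seed, resample
count, level, estimator, bands, config hash, and package version for
audit.

## Known limitations

* Percentile bootstrap intervals under-cover slightly at $n \approx 25$
  (per-distance false-positive rate a point or two above nominal); BCa or
  calibrated intervals are deliberately out of scope.
* The max/min test statistic has no power against pure size differences.
* The moment mean-form estimator is a mild shrinkage, not a full
  measurement-error correction.
* Landmark sets must be complete and shared across specimens; no
  missing-data handling, no Procrustes-based methods, no mesh or TPS
  format support.
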