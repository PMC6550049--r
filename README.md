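# edmorph

Euclidean Distance Matrix Analysis (EDMA) of 3D anatomical landmarks in R.

`edmorph` is for morphometricians and developmental biologists who compare
the 3D form of a structure — a newborn-mouse hemimandible, a skull, any
landmarked anatomy — between two groups of specimens (e.g. mutants vs
unaffected littermates) without superimposing coordinate systems. It
implements the full EDMA workflow: form matrices, mean-form estimation,
form-difference matrices with non-parametric bootstrap confidence
intervals, a bootstrap test of mean-form equality, effect-band
classification of significant distances, PCA of ln-transformed
inter-landmark distances, replicate-digitization QC, regional landmark
subsets, bilateral (left/right) asymmetry analysis, and a synthetic
landmark-data generator with known ground truth.

## The method

A configuration of *K* landmarks is represented by its **form matrix**

> FM = { d(p_i, p_j) : 1 ≤ i < j ≤ K },

the K(K−1)/2 unique Euclidean inter-landmark distances — invariant to
translation, rotation, and reflection, so no alignment step is needed and
mirrored (left/right) structures compare directly. For two samples, mean
forms are estimated per group (arithmetic per-distance mean by default; a
moment-based variance-shrinkage estimator is available) and compared by
the **form-difference matrix**

> FDM_ij = mean-form distance in the test group / like distance in the reference group,

so FDM_ij > 1 means that distance is larger in the test group. Inference
is non-parametric on specimens:

* **Per-distance confidence intervals** — specimens resampled with
  replacement within each group, mean forms and ratios recomputed,
  marginal percentile intervals (default level 0.90); a distance is
  significant when its interval excludes 1. Significant distances are
  banded by the point-estimate ratio into 5–10% and >10% increases and
  decreases, the conventional distance-map display.
* **Mean-form equality test** — statistic T = max(FDM)/min(FDM) (the
  spread of the ratios), null distribution from pooling all specimens and
  redrawing both pseudo-groups; p = (1 + #{T\* ≥ T_obs})/(1 + B).
* **Ordination** — PCA of the variance-covariance matrix of
  ln(distances), in form (size + shape) or scale-free shape
  (geometric-mean scaled) mode, with a centroid-vs-dispersion group
  separation summary.

All resampling is driven by one integer seed and reproduces
bit-identically.

## Worked example

Simulate a study — 16-landmark hemimandible-like template, 25 specimens
per group, coordinate noise 1% of the mean inter-landmark distance, and a
12% radial expansion of a 4-landmark posterior (ramus) subset in the
mutant group — then analyze it:

```r
library(edmorph)

tpl   <- make_template_form("mandible_16", seed = 3)
study <- simulate_two_group_study(tpl, effect_labels = rownames(tpl)[13:16],
                                  effect_size = 0.12, n_per_group = 25,
                                  seed = 42)

test_mean_form_difference(study$test, study$reference, n_boot = 5000, seed = 1)
#> <edma_form_test> bootstrap test of mean-form equality
#>   T = 2.8277 (max/min FDM ratio), p = 0.0002 (5000 resamples)

ci  <- bootstrap_fdm_intervals(study$test, study$reference,
                               n_boot = 5000, seed = 1)
cls <- classify_fdm_effects(ci)
cls
#> <edma_classification> 120 distances ( mutant / unaffected )
#>   decrease_gt10   decrease_5_10 significant_lt5 not_significant   increase_5_10
#>               2               3              31              54              21
#>   increase_gt10
#>               9

head(subset(cls$table, category == "increase_gt10"), 3)
#>     landmark_i landmark_j    ratio    lower    upper significant      category
#> 98      ram_01     ram_07 1.121063 1.108433 1.133685        TRUE increase_gt10
#> 112     ram_04     ram_06 1.109637 1.101126 1.118567        TRUE increase_gt10
#> 114     ram_04     ram_08 1.242269 1.218136 1.267359        TRUE increase_gt10
```

The mean forms differ (p = 0.0002, the add-one floor at 5000 resamples),
and the >10% increases concentrate on ramus–ramus distances — the planted
effect (ratios ≈ 1.12 within the expanded subset) recovered and correctly
localized.

The same machinery runs as one workflow over the whole set and regional
subsets, with per-unit FDM tables and a JSON report:

```r
cfg <- analysis_config(study$test, study$reference,
                       subsets = list(ramus = rownames(tpl)[9:16],
                                      body  = rownames(tpl)[1:8]),
                       n_boot = 2000, seed = 1, output_dir = "out")
run_full_analysis(cfg)
#> <edma_report> full analysis, seed 1 , 2000 resamples/unit
#>   whole            T=2.828 p=0.0004998  significant 67/120  PC1 85%  sep 6.78
#>   ramus            T=1.265 p=0.0004998  significant 24/28  PC1 65%  sep 6.19
#>   body             T=1.032 p=0.3758  significant 3/28  PC1 19%  sep 0.46
```

The affected ramus rejects strongly and separates cleanly on PC1; the
unaffected anterior body behaves like the null — the report's PCA
separation ratio (centroid distance over pooled within-group dispersion)
quantifies the scatter-plot impression. `run_asymmetry_analysis()` runs
the identical comparison between left and right sides after
`match_bilateral()` relabels right landmarks onto their left homologs.

See `vignettes/edma-methods.Rmd` for the estimators, resampling schemes,
design decisions, and known limitations.

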