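# Non-parametric bootstrap inference on form-difference matrices:
# percentile confidence intervals per distance, a mean-form equality test,
# and effect-band classification of significant distances.
#
# Reproducibility contract: every routine takes an integer seed; resample
# indices are drawn group-wise in a fixed order (group A then group B in
# each iteration), so identical inputs + seed give bit-identical results.

.resolve_groups <- function(group_a, group_b) {
  ga <- unique(specimen_groups(group_a))
  gb <- unique(specimen_groups(group_b))
  a <- if (length(ga) == 1L && ga != "all") ga else "A"
  b <- if (length(gb) == 1L && gb != "all") gb else "B"
  if (identical(a, b)) { a <- paste0(a, ".1"); b <- paste0(b, ".2") }
  c(a, b)
}

#' Bootstrap confidence intervals for the form-difference matrix
#'
#' For each of `n_boot` resamples, specimens are drawn with replacement
#' independently within each group (keeping the observed group sizes), the
#' two mean forms are re-estimated and their like-distance ratios
#' recomputed. Marginal two-sided percentile intervals at
#' `confidence_level` are taken per distance; a distance is flagged
#' significant when its interval excludes 1.
#'
#' @param group_a numerator (test) group, a [landmark_dataset()] with at
#'   least 2 specimens
#' @param group_b denominator (reference) group
#' @param n_boot number of bootstrap resamples (the reference analysis
#'   protocol uses 100,000)
#' @param confidence_level two-sided interval level (default 0.90)
#' @param seed integer seed; same seed and inputs reproduce the result
#'   bit-identically
#' @param estimator mean-form estimator, see [estimate_mean_form()]
#' @return an `edma_ci`: `table` (data.frame `landmark_i, landmark_j,
#'   ratio, lower, upper, significant`) plus `n_boot`,
#'   `confidence_level`, `seed`, `estimator` and the group labels
#' @export
bootstrap_fdm_intervals <- function(group_a, group_b, n_boot = 100000,
                                    confidence_level = 0.90, seed,
                                    estimator = c("arithmetic", "moment")) {
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("an integer `seed` is required")
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) stop("n_boot must be a positive integer")
  if (n_specimens(group_a) < 2L || n_specimens(group_b) < 2L)
    stop("both groups need at least 2 specimens")
  if (!identical(landmark_labels(group_a), landmark_labels(group_b)))
    stop("groups must share landmark labels in the same order")
  if (confidence_level <= 0 || confidence_level >= 1)
    stop("confidence_level must be in (0, 1)")

  da <- .distance_rows(group_a)
  db <- .distance_rows(group_b)
  na <- nrow(da); nb <- nrow(db)
  point <- .mean_form_distances(da, estimator)$distances /
           .mean_form_distances(db, estimator)$distances

  set.seed(seed)
  ratios <- matrix(NA_real_, n_boot, ncol(da))
  for (b in seq_len(n_boot)) {
    ia <- sample.int(na, na, replace = TRUE)
    ib <- sample.int(nb, nb, replace = TRUE)
    ratios[b, ] <- .mean_form_distances(da[ia, , drop = FALSE], estimator)$distances /
                   .mean_form_distances(db[ib, , drop = FALSE], estimator)$distances
  }
  alpha <- 1 - confidence_level
  lower <- apply(ratios, 2, stats::quantile, probs = alpha / 2, names = FALSE)
  upper <- apply(ratios, 2, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  pairs <- attr(da, "pairs")
  groups <- .resolve_groups(group_a, group_b)
  tab <- data.frame(pairs,
                    ratio = unname(point), lower = lower, upper = upper,
                    significant = lower > 1 | upper < 1,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_boot = n_boot,
                 confidence_level = confidence_level, seed = seed,
                 estimator = estimator,
                 numerator_group = groups[1], denominator_group = groups[2]),
            class = "edma_ci")
}

#' @export
print.edma_ci <- function(x, ...) {
  cat("<edma_ci>", nrow(x$table), "distances,",
      sprintf("%d%% percentile intervals, %d resamples\n",
              round(100 * x$confidence_level), x$n_boot))
  cat("  ", x$numerator_group, "/", x$denominator_group, "; significant:",
      sum(x$table$significant), "\n")
  invisible(x)
}

.t_statistic <- function(r) max(r) / min(r)

#' Bootstrap test of mean-form equality
#'
#' Tests the null hypothesis that two samples share the same mean form.
#' The statistic is `T = max(FDM) / min(FDM)`, the spread of the observed
#' like-distance ratios (1 when the mean forms are identical). The null
#' distribution is built by pooling all specimens and drawing both
#' pseudo-groups (at the observed sizes) with replacement from the pool,
#' recomputing `T*` for each resample. The p-value uses the add-one
#' estimator `(1 + #{T* >= T_obs}) / (1 + n_boot)` and is therefore never
#' exactly zero.
#'
#' @inheritParams bootstrap_fdm_intervals
#' @return an `edma_form_test`: `statistic`, `p_value`,
#'   `null_statistics`, `n_boot`, `seed`, `estimator`, group labels
#' @export
test_mean_form_difference <- function(group_a, group_b, n_boot = 100000,
                                      seed,
                                      estimator = c("arithmetic", "moment")) {
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("an integer `seed` is required")
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) stop("n_boot must be a positive integer")
  if (n_specimens(group_a) < 2L || n_specimens(group_b) < 2L)
    stop("both groups need at least 2 specimens")
  if (!identical(landmark_labels(group_a), landmark_labels(group_b)))
    stop("groups must share landmark labels in the same order")

  da <- .distance_rows(group_a)
  db <- .distance_rows(group_b)
  na <- nrow(da); nb <- nrow(db)
  t_obs <- .t_statistic(
    .mean_form_distances(da, estimator)$distances /
    .mean_form_distances(db, estimator)$distances)

  pool <- rbind(da, db)
  np <- nrow(pool)
  set.seed(seed)
  t_null <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ia <- sample.int(np, na, replace = TRUE)
    ib <- sample.int(np, nb, replace = TRUE)
    t_null[b] <- .t_statistic(
      .mean_form_distances(pool[ia, , drop = FALSE], estimator)$distances /
      .mean_form_distances(pool[ib, , drop = FALSE], estimator)$distances)
  }
  p <- (1 + sum(t_null >= t_obs)) / (1 + n_boot)
  groups <- .resolve_groups(group_a, group_b)
  structure(list(statistic = t_obs, p_value = p, null_statistics = t_null,
                 n_boot = n_boot, seed = seed, estimator = estimator,
                 numerator_group = groups[1], denominator_group = groups[2]),
            class = "edma_form_test")
}

#' @export
print.edma_form_test <- function(x, ...) {
  cat("<edma_form_test> bootstrap test of mean-form equality\n")
  cat(sprintf("  T = %.4f (max/min FDM ratio), p = %.4g (%d resamples)\n",
              x$statistic, x$p_value, x$n_boot))
  invisible(x)
}

.band_labels <- function(bands) {
  p1 <- formatC(100 * bands[1], format = "fg")
  p2 <- formatC(100 * bands[2], format = "fg")
  c(inc2 = sprintf("increase_gt%s", p2),
    inc1 = sprintf("increase_%s_%s", p1, p2),
    dec2 = sprintf("decrease_gt%s", p2),
    dec1 = sprintf("decrease_%s_%s", p1, p2),
    small = sprintf("significant_lt%s", p1),
    ns = "not_significant")
}

#' Classify significant distances into effect bands
#'
#' Reproduces the distance-map banding used to display localized group
#' differences: significant distances (interval excluding 1) are split
#' into moderate (5-10%) and large (>10%) increases or decreases by the
#' point-estimate ratio; significant distances that differ by less than
#' the first band are reported as `significant_lt5`; non-significant
#' distances are `not_significant` regardless of ratio.
#'
#' Decrease thresholds are multiplicative by default (`r <= 1/1.05`,
#' `r <= 1/1.10`), the natural symmetry for ratios; set
#' `decrease = "additive"` for `r <= 0.95`, `r <= 0.90`.
#'
#' @param ci an `edma_ci` from [bootstrap_fdm_intervals()]
#' @param bands two increasing fractions, default `c(0.05, 0.10)`
#' @param decrease `"multiplicative"` or `"additive"` decrease thresholds
#' @return an `edma_classification`: the CI `table` with a `category`
#'   factor column, plus `counts` per category and the thresholds used
#' @export
classify_fdm_effects <- function(ci, bands = c(0.05, 0.10),
                                 decrease = c("multiplicative", "additive")) {
  decrease <- match.arg(decrease)
  if (!inherits(ci, "edma_ci")) stop("`ci` must be an edma_ci")
  if (length(bands) != 2 || any(bands <= 0) || bands[1] >= bands[2])
    stop("`bands` must be two increasing positive fractions")
  lab <- .band_labels(bands)
  up1 <- 1 + bands[1]; up2 <- 1 + bands[2]
  if (decrease == "multiplicative") {
    lo1 <- 1 / up1; lo2 <- 1 / up2
  } else {
    lo1 <- 1 - bands[1]; lo2 <- 1 - bands[2]
  }
  r <- ci$table$ratio
  cat_ <- rep(lab["ns"], length(r))
  sig <- ci$table$significant
  cat_[sig] <- lab["small"]
  cat_[sig & r >= up1 & r < up2] <- lab["inc1"]
  cat_[sig & r >= up2] <- lab["inc2"]
  cat_[sig & r <= lo1 & r > lo2] <- lab["dec1"]
  cat_[sig & r <= lo2] <- lab["dec2"]
  levels <- unname(lab[c("dec2", "dec1", "small", "ns", "inc1", "inc2")])
  tab <- ci$table
  tab$category <- factor(cat_, levels = levels)
  structure(list(table = tab, counts = table(tab$category),
                 bands = bands, decrease = decrease,
                 thresholds = c(lower2 = lo2, lower1 = lo1,
                                upper1 = up1, upper2 = up2),
                 confidence_level = ci$confidence_level,
                 n_boot = ci$n_boot, seed = ci$seed,
                 numerator_group = ci$numerator_group,
                 denominator_group = ci$denominator_group),
            class = "edma_classification")
}

#' @export
print.edma_classification <- function(x, ...) {
  cat("<edma_classification>", nrow(x$table), "distances (",
      x$numerator_group, "/", x$denominator_group, ")\n")
  print(x$counts)
  invisible(x)
}
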