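# Synthetic two-group landmark data with known truth: template mean
# forms, isotropic Gaussian landmark perturbation, localized regional
# effects, and replicate-digitization noise. All generators are pure
# functions of their arguments and seed.

#' Deterministic template landmark configurations
#'
#' * `toy_triangle`: 3 landmarks at (0,0,0), (3,0,0), (0,4,0) mm — the
#'   3-4-5 triangle.
#' * `box_8`: the 8 corners of a 5 mm cube.
#' * `mandible_16`: 16 labeled pseudo-random landmarks in a
#'   10 x 4 x 3 mm box (roughly a newborn-mouse hemimandible envelope),
#'   reproducible for a given `seed`, with a minimum inter-landmark
#'   separation of 0.5 mm. Labels follow anatomical regions: 8
#'   anterior-body landmarks (`bod_*`) and 8 ramus landmarks (`ram_*`,
#'   condylar/coronoid/angular processes).
#'
#' @param kind template name
#' @param seed integer seed (used by `mandible_16` only)
#' @return a `K x 3` coordinate matrix (mm) with landmark labels as
#'   rownames
#' @export
make_template_form <- function(kind = c("toy_triangle", "box_8", "mandible_16"),
                               seed = 1) {
  kind <- match.arg(kind)
  if (kind == "toy_triangle") {
    m <- rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(0, 4, 0))
    colnames(m) <- c("x", "y", "z")
    return(m)
  }
  if (kind == "box_8") {
    g <- as.matrix(expand.grid(x = c(0, 5), y = c(0, 5), z = c(0, 5)))
    rownames(g) <- sprintf("c%d", 1:8)
    return(g)
  }
  # mandible_16: rejection-sample until all pairwise distances >= 0.5 mm
  labels <- c(sprintf("bod_%02d", 1:8), sprintf("ram_%02d", 1:8))
  set.seed(seed)
  repeat {
    m <- cbind(x = stats::runif(16, 0, 10),
               y = stats::runif(16, 0, 4),
               z = stats::runif(16, 0, 3))
    if (min(stats::dist(m)) >= 0.5) break
  }
  # anterior body occupies the front half, ramus the back half of x
  m[1:8, 1] <- m[1:8, 1] * 0.5
  m[9:16, 1] <- 5 + m[9:16, 1] * 0.5
  rownames(m) <- labels
  m
}

#' Apply a localized regional effect to a template
#'
#' Creates a known ground-truth group difference. `radial_scale` moves
#' each affected landmark away from the centroid of the affected set by a
#' factor `1 + magnitude` (so distances within the affected set scale by
#' exactly `1 + magnitude` and distances among unaffected landmarks are
#' untouched). `displacement` adds a fixed 3-vector (mm) to each affected
#' landmark.
#'
#' @param template `K x 3` coordinate matrix with rownames
#' @param labels landmarks to affect
#' @param mode `"radial_scale"` or `"displacement"`
#' @param magnitude scalar scale fraction (e.g. 0.12 for +12%) or a
#'   length-3 displacement vector in mm
#' @return the modified template matrix
#' @export
apply_regional_effect <- function(template, labels,
                                  mode = c("radial_scale", "displacement"),
                                  magnitude) {
  mode <- match.arg(mode)
  template <- as.matrix(template)
  unknown <- setdiff(labels, rownames(template))
  if (length(unknown)) stop("unknown landmark label '", unknown[1], "'")
  idx <- match(labels, rownames(template))
  if (mode == "radial_scale") {
    if (length(magnitude) != 1 || !is.finite(magnitude) || magnitude <= -1)
      stop("radial_scale magnitude must be a single value > -1")
    ctr <- colMeans(template[idx, , drop = FALSE])
    template[idx, ] <- sweep(sweep(template[idx, , drop = FALSE], 2, ctr),
                             1, rep(1 + magnitude, length(idx)), "*")
    template[idx, ] <- sweep(template[idx, , drop = FALSE], 2, ctr, "+")
  } else {
    if (length(magnitude) != 3 || any(!is.finite(magnitude)))
      stop("displacement magnitude must be a length-3 vector (mm)")
    template[idx, ] <- sweep(template[idx, , drop = FALSE], 2, magnitude, "+")
  }
  template
}

#' Simulate a group of specimens around a template form
#'
#' Each specimen is the template plus independent Gaussian noise of
#' standard deviation `sigma` (mm) on every coordinate of every landmark
#' — the classical perturbation model underlying EDMA estimation.
#' `sigma` may be a single value or one value per landmark
#' (heteroscedastic digitization error).
#'
#' @param template `K x 3` coordinate matrix with rownames
#' @param n number of specimens
#' @param sigma coordinate noise SD in mm (scalar or length-K)
#' @param group_label group label for all specimens (also the specimen id
#'   prefix)
#' @param seed integer seed
#' @return a [landmark_dataset()]
#' @export
simulate_group <- function(template, n, sigma, group_label = "A", seed) {
  if (missing(seed)) stop("an integer `seed` is required")
  template <- as.matrix(template)
  K <- nrow(template)
  if (n < 1) stop("n must be at least 1")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (!length(sigma) %in% c(1L, K))
    stop("sigma must be a scalar or one value per landmark")
  sig <- if (length(sigma) == 1L) matrix(sigma, K, 3) else matrix(sigma, K, 3)
  set.seed(seed)
  coords <- array(NA_real_, c(K, 3, n),
                  dimnames = list(rownames(template), c("x", "y", "z"),
                                  sprintf("%s_%03d", group_label, seq_len(n))))
  for (i in seq_len(n)) {
    coords[, , i] <- template + matrix(stats::rnorm(K * 3), K, 3) * sig
  }
  landmark_dataset(coords, rep(group_label, n))
}

#' Simulate a replicate digitization pair
#'
#' Produces two independent noisy digitization trials of every specimen
#' in a dataset: each trial is the specimen's coordinates plus Gaussian
#' noise of SD `digitization_sd` (mm) per coordinate. Averaging the two
#' trials with [average_digitization_trials()] recovers the latent
#' coordinates with the error variance halved.
#'
#' @param dataset a [landmark_dataset()] of latent (true) configurations
#' @param digitization_sd per-coordinate digitization noise SD in mm
#' @param seed integer seed
#' @return list with `trial_a` and `trial_b`, both `landmark_dataset`s
#' @export
simulate_digitization_pair <- function(dataset, digitization_sd, seed) {
  if (missing(seed)) stop("an integer `seed` is required")
  if (length(digitization_sd) != 1 || digitization_sd < 0)
    stop("digitization_sd must be a single non-negative value")
  dims <- dim(dataset$coords)
  set.seed(seed)
  noise_a <- array(stats::rnorm(prod(dims), sd = digitization_sd), dims)
  noise_b <- array(stats::rnorm(prod(dims), sd = digitization_sd), dims)
  list(trial_a = landmark_dataset(dataset$coords + noise_a, dataset$groups),
       trial_b = landmark_dataset(dataset$coords + noise_b, dataset$groups))
}

#' Simulate a complete two-group study
#'
#' Convenience wrapper producing a mutant-vs-unaffected style design: a
#' reference group drawn around `template` and a test group drawn around
#' `apply_regional_effect(template, ...)`. Defaults reflect a realistic
#' small-rodent cross-sectional study: n = 25 per group and coordinate
#' noise around 1-2% of the mean inter-landmark distance.
#'
#' @param template `K x 3` template matrix
#' @param effect_labels landmarks carrying the effect (NULL for a null
#'   design)
#' @param effect_size radial scale fraction for the affected set
#' @param n_per_group specimens per group
#' @param sigma coordinate noise SD in mm; default 1% of the template's
#'   mean inter-landmark distance
#' @param seed integer seed (consumes `seed` and `seed + 1`)
#' @return list with `reference` and `test` datasets plus the two
#'   templates
#' @export
simulate_two_group_study <- function(template, effect_labels = NULL,
                                     effect_size = 0.12, n_per_group = 25,
                                     sigma = NULL, seed) {
  if (missing(seed)) stop("an integer `seed` is required")
  template <- as.matrix(template)
  if (is.null(sigma)) sigma <- 0.01 * mean(stats::dist(template))
  test_template <- if (is.null(effect_labels)) template
    else apply_regional_effect(template, effect_labels,
                               "radial_scale", effect_size)
  list(reference = simulate_group(template, n_per_group, sigma,
                                  "unaffected", seed),
       test = simulate_group(test_template, n_per_group, sigma,
                             "mutant", seed + 1),
       template_reference = template, template_test = test_template)
}
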