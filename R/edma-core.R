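# Deterministic EDMA core: form matrices, mean forms, form-difference
# matrices, and geometric-mean scaling to shape space.

.DIST_FLOOR <- 1e-9  # mm; below this two landmarks are treated as coincident

# n x P matrix of inter-landmark distances, one row per specimen, columns
# in canonical pair order (matches pair_index / stats::dist storage).
.distance_rows <- function(dataset) {
  n <- n_specimens(dataset)
  K <- n_landmarks(dataset)
  out <- matrix(NA_real_, n, K * (K - 1L) / 2L)
  for (i in seq_len(n)) out[i, ] <- as.vector(stats::dist(dataset$coords[, , i]))
  pairs <- pair_index(landmark_labels(dataset))
  dimnames(out) <- list(specimen_ids(dataset), .pair_names(pairs))
  attr(out, "pairs") <- pairs
  out
}

.new_form_matrix <- function(distances, pairs, labels) {
  structure(list(distances = as.numeric(distances), pairs = pairs,
                 labels = labels), class = "form_matrix")
}

#' Compute the form matrix of one landmark configuration
#'
#' The form matrix is the vector of all `K(K-1)/2` unique Euclidean
#' distances among the `K` landmarks of a single specimen — a
#' representation of form that is invariant to translation, rotation and
#' reflection of the coordinate system.
#'
#' @param x a `K x 3` coordinate matrix with landmark labels as rownames,
#'   or a [landmark_dataset()]
#' @param specimen when `x` is a dataset with several specimens, the
#'   specimen id to use
#' @return a `form_matrix`: `distances` (mm) in canonical pair order plus
#'   the `pairs` index
#' @export
compute_form_matrix <- function(x, specimen = NULL) {
  if (inherits(x, "landmark_dataset")) {
    if (is.null(specimen)) {
      if (n_specimens(x) != 1L)
        stop("dataset has several specimens; give `specimen`")
      specimen <- specimen_ids(x)[1]
    }
    labels <- landmark_labels(x)
    coords <- x$coords[, , specimen]
  } else {
    coords <- as.matrix(x)
    if (ncol(coords) != 3) stop("coordinates must be K x 3")
    if (nrow(coords) < 3) stop("need at least 3 landmarks")
    labels <- rownames(coords)
    if (is.null(labels)) labels <- sprintf("lm%02d", seq_len(nrow(coords)))
  }
  d <- as.vector(stats::dist(coords))
  pairs <- pair_index(labels)
  small <- which(d < .DIST_FLOOR)
  if (length(small)) {
    p <- pairs[small[1], ]
    stop("coincident landmarks '", p$landmark_i, "' and '", p$landmark_j,
         "' (distance below ", .DIST_FLOOR, " mm)")
  }
  .new_form_matrix(d, pairs, labels)
}

#' @export
print.form_matrix <- function(x, ...) {
  cat("<form_matrix>", length(x$distances), "unique distances among",
      length(x$labels), "landmarks\n")
  cat(sprintf("  range: %.4g - %.4g mm\n",
              min(x$distances), max(x$distances)))
  invisible(x)
}

# Mean-form distances from an n x P distance-row matrix.
# arithmetic: per-pair mean of observed distances.
# moment: per-pair sqrt(max(mean(d^2) - var(d), eps)) — shrinks the
# squared-distance average by the observed distance variance; falls back
# to the arithmetic mean for pairs where the correction is non-positive.
.mean_form_distances <- function(rows, estimator, eps = .DIST_FLOOR^2) {
  n <- nrow(rows)
  arith <- colSums(rows) / n
  if (estimator == "arithmetic")
    return(list(distances = arith, fallback = character(0)))
  if (n < 2L) stop("moment estimator needs at least 2 specimens")
  msq <- colSums(rows^2) / n
  v <- pmax((msq - arith^2) * n / (n - 1), 0)  # sample variance
  corrected <- msq - v
  bad <- corrected <= eps
  dist <- sqrt(pmax(corrected, eps))
  dist[bad] <- arith[bad]
  list(distances = dist, fallback = colnames(rows)[bad])
}

#' Estimate the sample mean form
#'
#' Averages the form matrices of a sample of specimens into a mean form.
#' The `arithmetic` estimator (default) is the per-pair mean of the
#' observed distances. The `moment` estimator is
#' `sqrt(max(mean(d^2) - var(d), eps))` per pair — a variance-based
#' shrinkage of the squared-distance average that counteracts the upward
#' bias of averaged distances under additive landmark noise; where the
#' correction would be non-positive the arithmetic mean is used instead
#' and the pair is recorded in `fallback`.
#'
#' @param dataset a [landmark_dataset()]; usually a single group (see
#'   [filter_group()]). All specimens present are used.
#' @param estimator `"arithmetic"` or `"moment"`
#' @return a `mean_form`: `distances`, `pairs`, per-pair `dispersion`
#'   (sample variance of the distance, `NA` when n = 1), `n`, `estimator`,
#'   `group` (the group label when unique) and `fallback`
#' @export
estimate_mean_form <- function(dataset, estimator = c("arithmetic", "moment")) {
  estimator <- match.arg(estimator)
  if (!inherits(dataset, "landmark_dataset")) stop("not a landmark_dataset")
  n <- n_specimens(dataset)
  if (n < 1L) stop("empty sample")
  if (estimator == "moment" && n < 2L)
    stop("moment estimator needs at least 2 specimens")
  rows <- .distance_rows(dataset)
  if (any(rows < .DIST_FLOOR)) {
    idx <- which(rows < .DIST_FLOOR, arr.ind = TRUE)[1, ]
    p <- attr(rows, "pairs")[idx[2], ]
    stop("coincident landmarks '", p$landmark_i, "' and '", p$landmark_j,
         "' in specimen '", rownames(rows)[idx[1]], "'")
  }
  est <- .mean_form_distances(rows, estimator)
  disp <- if (n >= 2L) apply(rows, 2, stats::var) else rep(NA_real_, ncol(rows))
  g <- unique(specimen_groups(dataset))
  structure(list(distances = unname(est$distances),
                 pairs = attr(rows, "pairs"),
                 labels = landmark_labels(dataset),
                 dispersion = unname(disp),
                 n = n, estimator = estimator,
                 group = if (length(g) == 1L) g else NA_character_,
                 fallback = est$fallback),
            class = "mean_form")
}

#' @export
print.mean_form <- function(x, ...) {
  cat("<mean_form>", length(x$distances), "distances,",
      x$estimator, "estimator, n =", x$n, "\n")
  if (!is.na(x$group)) cat("  group:", x$group, "\n")
  if (length(x$fallback))
    cat("  arithmetic fallback for", length(x$fallback), "pair(s)\n")
  invisible(x)
}

#' Form-difference matrix of two mean forms
#'
#' Element-wise ratios of like inter-landmark distances,
#' numerator / denominator. By convention the numerator is the test group
#' (e.g. mutant) and the denominator the reference group (e.g. unaffected
#' littermates), so a ratio above 1 means the distance is larger in the
#' test group.
#'
#' @param numerator,denominator `mean_form` (or `form_matrix`) objects
#'   sharing the same pair index
#' @return a `form_difference`: `ratios`, `pairs`, `numerator_group`,
#'   `denominator_group`
#' @export
compute_fdm <- function(numerator, denominator) {
  grab <- function(x) {
    if (inherits(x, "form_matrix"))
      list(d = x$distances, pairs = x$pairs, group = NA_character_)
    else if (inherits(x, "mean_form"))
      list(d = x$distances, pairs = x$pairs, group = x$group)
    else stop("inputs must be mean_form or form_matrix objects")
  }
  a <- grab(numerator); b <- grab(denominator)
  if (!identical(a$pairs, b$pairs))
    stop("pair indexes differ; both inputs must share landmark labels and order")
  structure(list(ratios = a$d / b$d, pairs = a$pairs,
                 numerator_group = a$group, denominator_group = b$group),
            class = "form_difference")
}

#' @export
print.form_difference <- function(x, ...) {
  cat("<form_difference>", length(x$ratios), "distance ratios (",
      x$numerator_group, "/", x$denominator_group, ")\n")
  cat(sprintf("  range: %.4f - %.4f\n", min(x$ratios), max(x$ratios)))
  invisible(x)
}

#' Scale a form to shape space
#'
#' Divides every inter-landmark distance by the geometric mean of all
#' distances, so the result is scale-free with geometric mean exactly 1.
#' For a `mean_form` the per-pair dispersion is rescaled by the squared
#' factor.
#'
#' @param fm a `form_matrix` or `mean_form`
#' @return object of the same class, geometric-mean scaled
#' @export
scale_to_shape <- function(fm) {
  gm <- function(d) exp(mean(log(d)))
  if (inherits(fm, "form_matrix")) {
    fm$distances <- fm$distances / gm(fm$distances)
  } else if (inherits(fm, "mean_form")) {
    g <- gm(fm$distances)
    fm$distances <- fm$distances / g
    fm$dispersion <- fm$dispersion / g^2
  } else stop("scale_to_shape needs a form_matrix or mean_form")
  fm
}
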