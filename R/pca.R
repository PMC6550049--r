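# PCA of ln-transformed inter-landmark distances. Form mode keeps size and
# shape together; scale-free mode removes per-specimen scale by
# geometric-mean scaling (equivalently, row-centering in log space).

#' Table of ln-transformed inter-landmark distances
#'
#' One row per specimen, one column per unique landmark pair (canonical
#' order, see [pair_index()]), entries `ln(distance in mm)`. With
#' `scale_free = TRUE` each specimen's distances are geometric-mean scaled
#' first, which in log space is centering each row by its mean; the
#' resulting rows are invariant to uniform scaling of a specimen.
#'
#' @param dataset a [landmark_dataset()]
#' @param scale_free remove per-specimen scale (default `FALSE`, i.e.
#'   form = size and shape together)
#' @return a numeric matrix of class `distance_table` with attributes
#'   `groups`, `pairs` and `scale_free`
#' @export
ln_distance_table <- function(dataset, scale_free = FALSE) {
  rows <- .distance_rows(dataset)
  if (any(rows < .DIST_FLOOR)) {
    idx <- which(rows < .DIST_FLOOR, arr.ind = TRUE)[1, ]
    p <- attr(rows, "pairs")[idx[2], ]
    stop("coincident landmarks '", p$landmark_i, "' and '", p$landmark_j,
         "' in specimen '", rownames(rows)[idx[1]], "'")
  }
  tab <- log(rows)
  if (scale_free) tab <- tab - rowMeans(tab)
  structure(tab, groups = unname(specimen_groups(dataset)),
            pairs = attr(rows, "pairs"), scale_free = scale_free,
            class = c("distance_table", "matrix"))
}

#' Principal component analysis of a ln-distance table
#'
#' Eigendecomposition of the column variance-covariance matrix of the
#' table (covariance, not correlation). When there are more landmark
#' pairs than specimens the decomposition is carried out through the
#' specimen-space inner-product matrix, which has the same non-zero
#' spectrum; results are identical either way. Components use a
#' deterministic sign convention: each is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param table a `distance_table` from [ln_distance_table()] (any numeric
#'   specimens x variables matrix is accepted)
#' @param n_components number of components to keep; default
#'   `min(n_specimens - 1, n_pairs)`
#' @return a `shape_pca`: `scores` (specimens x components, zero column
#'   means), `loadings` (pairs x components, orthonormal columns),
#'   `explained` (fraction of total variance per component),
#'   `total_variance`, and the row `groups` when present
#' @export
run_pca <- function(table, n_components = NULL) {
  x <- unclass(table)
  if (!is.matrix(x) || !is.numeric(x)) stop("`table` must be a numeric matrix")
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("PCA needs at least 2 specimens")
  kmax <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- kmax
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be between 1 and min(specimens - 1, pairs) = ", kmax)
  xc <- scale(x, center = TRUE, scale = FALSE)
  total_var <- sum(xc^2) / (n - 1)
  if (p <= n) {
    ee <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
    values <- ee$values
    loadings <- ee$vectors[, seq_len(n_components), drop = FALSE]
  } else {
    ee <- eigen(tcrossprod(xc) / (n - 1), symmetric = TRUE)
    values <- ee$values
    lam <- values[seq_len(n_components)]
    loadings <- crossprod(xc, ee$vectors[, seq_len(n_components), drop = FALSE])
    loadings <- sweep(loadings, 2, sqrt(pmax(lam, .Machine$double.eps) * (n - 1)), "/")
  }
  # orient: largest-magnitude loading positive (first index breaks ties)
  for (k in seq_len(n_components)) {
    m <- which.max(abs(loadings[, k]))
    if (loadings[m, k] < 0) loadings[, k] <- -loadings[, k]
  }
  scores <- xc %*% loadings
  explained <- pmax(values[seq_len(n_components)], 0) / total_var
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(rownames(x), colnames(loadings))
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, total_variance = total_var,
                 eigenvalues = pmax(values, 0),
                 n_components = n_components,
                 groups = attr(table, "groups"),
                 scale_free = isTRUE(attr(table, "scale_free"))),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("<shape_pca>", nrow(x$scores), "specimens,", x$n_components,
      "components", if (x$scale_free) "(scale-free shape)" else "(form)", "\n")
  ev <- utils::head(x$explained, 5)
  cat("  explained:", paste(sprintf("%.1f%%", 100 * ev), collapse = " "),
      if (x$n_components > 5) "..." else "", "\n")
  invisible(x)
}

#' Group separation in PC score space
#'
#' Measures how well groups separate in a chosen score subspace: the
#' distance between group centroids, the pooled within-group dispersion
#' (root of the pooled per-dimension within-group variance, so the value
#' is comparable across subspace dimensions), and their ratio. With more
#' than two groups the centroid distance is the mean over group pairs.
#'
#' @param result a `shape_pca` from [run_pca()]
#' @param groups group label per specimen; defaults to the labels carried
#'   by the PCA result
#' @param components which components span the subspace (default 1:2)
#' @return list with `centroid_distance`, `within_dispersion`, `ratio`,
#'   `components`, and the per-group centroids
#' @export
group_separation <- function(result, groups = NULL, components = c(1, 2)) {
  if (!inherits(result, "shape_pca")) stop("`result` must be a shape_pca")
  if (is.null(groups)) groups <- result$groups
  if (is.null(groups)) stop("no group labels available")
  if (length(groups) != nrow(result$scores))
    stop("`groups` must have one label per specimen")
  components <- as.integer(components)
  if (any(components < 1L) || any(components > result$n_components))
    stop("components out of range")
  s <- result$scores[, components, drop = FALSE]
  gs <- unique(groups)
  if (length(gs) < 2L) stop("need at least 2 groups")
  centroids <- matrix(NA_real_, length(gs), ncol(s),
                      dimnames = list(gs, colnames(s)))
  for (g in gs) centroids[g, ] <- colMeans(s[groups == g, , drop = FALSE])
  pd <- as.vector(stats::dist(centroids))
  centroid_distance <- mean(pd)
  ss <- 0
  for (g in gs) {
    sg <- s[groups == g, , drop = FALSE]
    ss <- ss + sum(sweep(sg, 2, centroids[g, ])^2)
  }
  within_var <- ss / ((nrow(s) - length(gs)) * ncol(s))
  within_dispersion <- sqrt(within_var)
  list(centroid_distance = centroid_distance,
       within_dispersion = within_dispersion,
       ratio = if (within_dispersion > 0) centroid_distance / within_dispersion
               else Inf,
       components = components, centroids = centroids)
}
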