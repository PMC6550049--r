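# Shared fixtures and independent oracles.
#
# The oracle functions re-implement distance computation, mean forms and
# the bootstrap resampling loop with plain double loops / sum(), entirely
# independent of the package internals, so they can certify the
# implementation bit-for-bit at small n_boot.

right_triangle <- function() {
  m <- rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(0, 4, 0))
  colnames(m) <- c("x", "y", "z")
  m
}

# random rotation (optionally improper, i.e. with reflection) + translation
random_rigid <- function(reflect = NA) {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (is.na(reflect)) reflect <- stats::runif(1) < 0.5
  if (xor(det(Q) < 0, reflect)) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(X, tr) sweep(X %*% tr$R, 2, tr$t, "+")

# template with 5 left landmarks and their exact mirror images (x -> -x)
symmetric_template <- function(seed = 7, n_side = 5) {
  set.seed(seed)
  left <- cbind(x = stats::runif(n_side, 1, 4),
                y = stats::runif(n_side, 0, 4),
                z = stats::runif(n_side, 0, 3))
  rownames(left) <- sprintf("L%d", seq_len(n_side))
  right <- left
  right[, 1] <- -right[, 1]
  rownames(right) <- sprintf("R%d", seq_len(n_side))
  rbind(left, right)
}

bilateral_pairing <- function(n_side = 5) {
  data.frame(left = sprintf("L%d", seq_len(n_side)),
             right = sprintf("R%d", seq_len(n_side)),
             stringsAsFactors = FALSE)
}

# ---- brute-force oracles --------------------------------------------------

oracle_distance_rows <- function(ds) {
  n <- n_specimens(ds)
  K <- n_landmarks(ds)
  out <- matrix(NA_real_, n, K * (K - 1) / 2)
  for (i in seq_len(n)) {
    X <- ds$coords[, , i]
    col <- 0L
    for (a in seq_len(K - 1)) {
      for (b in (a + 1):K) {
        col <- col + 1L
        dx <- X[a, 1] - X[b, 1]
        dy <- X[a, 2] - X[b, 2]
        dz <- X[a, 3] - X[b, 3]
        out[i, col] <- sqrt(dx * dx + dy * dy + dz * dz)
      }
    }
  }
  out
}

oracle_colmean <- function(m) apply(m, 2, function(col) sum(col) / length(col))

oracle_bootstrap_ci <- function(group_a, group_b, n_boot, level, seed) {
  da <- oracle_distance_rows(group_a)
  db <- oracle_distance_rows(group_b)
  point <- oracle_colmean(da) / oracle_colmean(db)
  set.seed(seed)
  r <- matrix(NA_real_, n_boot, ncol(da))
  for (b in seq_len(n_boot)) {
    ia <- sample.int(nrow(da), nrow(da), replace = TRUE)
    ib <- sample.int(nrow(db), nrow(db), replace = TRUE)
    r[b, ] <- oracle_colmean(da[ia, , drop = FALSE]) /
              oracle_colmean(db[ib, , drop = FALSE])
  }
  alpha <- 1 - level
  list(ratio = point,
       lower = apply(r, 2, stats::quantile, probs = alpha / 2, names = FALSE),
       upper = apply(r, 2, stats::quantile, probs = 1 - alpha / 2,
                     names = FALSE))
}

oracle_form_test <- function(group_a, group_b, n_boot, seed) {
  da <- oracle_distance_rows(group_a)
  db <- oracle_distance_rows(group_b)
  tstat <- function(r) max(r) / min(r)
  t_obs <- tstat(oracle_colmean(da) / oracle_colmean(db))
  pool <- rbind(da, db)
  set.seed(seed)
  tn <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ia <- sample.int(nrow(pool), nrow(da), replace = TRUE)
    ib <- sample.int(nrow(pool), nrow(db), replace = TRUE)
    tn[b] <- tstat(oracle_colmean(pool[ia, , drop = FALSE]) /
                   oracle_colmean(pool[ib, , drop = FALSE]))
  }
  list(statistic = t_obs, p_value = (1 + sum(tn >= t_obs)) / (1 + n_boot))
}

# minimal hand-built CI object for classification tests
fake_ci <- function(ratio, significant, level = 0.90) {
  k <- length(ratio)
  pairs <- pair_index(sprintf("l%d", seq_len(ceiling((1 + sqrt(1 + 8 * k)) / 2))))
  pairs <- pairs[seq_len(k), ]
  structure(list(table = data.frame(pairs, ratio = ratio,
                                    lower = ifelse(significant & ratio > 1, 1.001,
                                            ifelse(significant, ratio * 0.99, 0.9)),
                                    upper = ifelse(significant & ratio > 1, ratio * 1.01,
                                            ifelse(significant, 0.999, 1.1)),
                                    significant = significant,
                                    stringsAsFactors = FALSE),
                 n_boot = 100L, confidence_level = level, seed = 1L,
                 estimator = "arithmetic",
                 numerator_group = "mutant", denominator_group = "unaffected"),
            class = "edma_ci")
}
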