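# Independent oracles used by the tests.  These deliberately re-derive
# quantities by brute force / enumeration, on different code paths from
# the implementation they check.

# Exhaustive grid search for the MSE-optimal beta-kernel bandwidth.
oracle_grid_bandwidth <- function(values, n_bins,
                                  grid = seq(0.01, 0.5, by = 0.001)) {
  z <- seq(0, 1, length.out = n_bins)
  idx <- pmin(floor(values * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  d_hist <- (counts / (length(values) / n_bins))[pmin(floor(z * n_bins) + 1L, n_bins)]
  mse <- vapply(grid, function(bw) {
    a <- 1 + z / bw
    b <- 1 + (1 - z) / bw
    D <- vapply(seq_along(z), function(j) {
      mean(stats::dbeta(values, a[j], b[j]))
    }, numeric(1))
    mean((d_hist - D)^2)
  }, numeric(1))
  list(bw = grid[which.min(mse)], mse = mse, grid = grid)
}

# Knee detection by direct angle enumeration (acos on raw vectors).
oracle_knee <- function(bic) {
  b <- (bic - min(bic)) / (max(bic) - min(bic))
  m <- length(bic)
  angles <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    convex <- (b[i - 1] + b[i + 1]) / 2 - b[i]
    if (convex <= 1e-12) next
    u <- c(i - 1, b[i - 1]) - c(i, b[i])
    v <- c(i + 1, b[i + 1]) - c(i, b[i])
    angles[i] <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  if (all(is.na(angles))) 2L else which.min(angles)
}

# Confusion-matrix metrics by direct counting.
oracle_confusion_metrics <- function(probs, y, thr = 0.5) {
  pred <- ifelse(probs >= thr, 1, 0)
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(y)) {
    if (pred[i] == 1 && y[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && y[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && y[i] == 1) fn <- fn + 1
    if (pred[i] == 0 && y[i] == 0) tn <- tn + 1
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = (tp + tn) / length(y),
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
       mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0,
       brier = mean((probs - y)^2))
}

# AUC as the rank-sum (Mann-Whitney) statistic with tie correction.
oracle_auc <- function(probs, y) {
  r <- rank(probs)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A separable 1-feature PU dataset: positives at +1, unlabeled at -1.
toy_separable <- function(n_pos = 20, n_unl = 80) {
  x <- matrix(c(rep(1, n_pos), rep(-1, n_unl)), ncol = 1)
  pu_dataset(x, s = c(rep(1L, n_pos), rep(0L, n_unl)))
}

# Piecewise density pair D_u = alpha*D_p + (1-alpha)*D_n on a shared grid,
# with D_n supported away from D_p's mode (disjoint high-density regions),
# used by the oracle-equivalence suite.
constructed_density_pair <- function(alpha, n_bins = 101, sep_frac = 0.45) {
  z <- seq(0, 1, length.out = n_bins)
  # positives concentrated near 1, negatives near 0
  dp <- stats::dbeta(z, 6, 2)
  dn <- stats::dbeta(z, 2, 10)
  dn[z > sep_frac + 0.3] <- 0  # hard-truncate so D_n vanishes where D_p peaks
  du <- alpha * dp + (1 - alpha) * dn
  list(
    Du = structure(list(z = z, D = du, bw = 0.1, n_bins = n_bins),
                   class = "density_grid"),
    Dp = structure(list(z = z, D = dp, bw = 0.1, n_bins = n_bins),
                   class = "density_grid")
  )
}
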