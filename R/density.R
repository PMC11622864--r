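# Density estimation on [0, 1]: beta-kernel estimates, histogram-derived
# densities, bin-count heuristics, and MSE-optimal bandwidth selection.

BW_RANGE <- c(0.01, 0.5)

density_grid <- function(z, D, bw, n_bins, bin_density = NULL) {
  structure(list(z = z, D = D, bw = bw, n_bins = as.integer(n_bins),
                 bin_density = bin_density),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density grid: %d points on [0,1], bw = %s, mass (trapezoid) = %.4f\n",
              x$n_bins, ifelse(is.na(x$bw), "NA", format(x$bw)),
              trapezoid_mass(x)))
  invisible(x)
}

# Trapezoidal integral of a density grid over [0, 1].
trapezoid_mass <- function(grid) {
  z <- grid$z; D <- grid$D
  sum(diff(z) * (utils::head(D, -1) + utils::tail(D, -1)) / 2)
}

# Precompute the bandwidth-free part of the beta-kernel log density:
# S[i, j] = z_j * log(x_i) + (1 - z_j) * log(1 - x_i).
# The full log kernel at bandwidth bw is S / bw + lgamma-normaliser(z, bw).
# Columns at z = 0 / z = 1 are fixed so that exact data values 0 and 1
# contribute their correct boundary density (0 * log(0) := 0).
beta_kernel_core <- function(values, z) {
  lx <- log(values)
  l1x <- log1p(-values)
  S <- outer(lx, z) + outer(l1x, 1 - z)
  if (any(values == 0)) {
    i <- which(values == 0)
    S[i, ] <- outer(rep(1, length(i)), ifelse(z == 0, 0, -Inf))
  }
  if (any(values == 1)) {
    i <- which(values == 1)
    S[i, ] <- outer(rep(1, length(i)), ifelse(z == 1, 0, -Inf))
  }
  S
}

beta_kernel_eval <- function(S, z, bw) {
  a <- 1 + z / bw
  b <- 1 + (1 - z) / bw
  lc <- lgamma(a + b) - lgamma(a) - lgamma(b)
  M <- exp(sweep(S / bw, 2, lc, "+"))
  colMeans(M)
}

#' Beta-kernel density estimate on the unit interval
#'
#' Estimates the density of probabilities `values` at `n_bins` equispaced
#' points `z` spanning \[0, 1\], as the average over data points `x` of the
#' Beta density
#' \deqn{h(x; a, b) = \frac{\Gamma(a+b)}{\Gamma(a)\Gamma(b)}
#'       x^{a-1}(1-x)^{b-1}, \quad a = 1 + z/bw,\ b = 1 + (1-z)/bw.}
#' Because each kernel lives on \[0, 1\] the estimate is free of the
#' boundary bias of Gaussian kernels and is nonnegative everywhere — a
#' requirement of the mixture-gap objective, which breaks down if density
#' estimates dip below zero.
#'
#' @param values probability vector in \[0, 1\] (at least one value).
#' @param bw bandwidth, in \[0.01, 0.5\].
#' @param n_bins number of grid points (>= 2).
#' @return A `density_grid`: list with `z`, `D`, `bw`, `n_bins`.
#' @examples
#' g <- beta_kernel_density(c(0.3), bw = 0.5, n_bins = 3)
#' g$D[1]  # 3 * (1 - 0.3)^2 = 1.47
#' @export
beta_kernel_density <- function(values, bw, n_bins) {
  check_prob_vector(values)
  if (length(bw) != 1 || !is.finite(bw) || bw < BW_RANGE[1] || bw > BW_RANGE[2]) {
    stop(sprintf("'bw' must lie in [%g, %g]", BW_RANGE[1], BW_RANGE[2]),
         call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  z <- seq(0, 1, length.out = n_bins)
  D <- beta_kernel_eval(beta_kernel_core(values, z), z, bw)
  density_grid(z, D, bw, n_bins)
}

#' Histogram bin-count heuristics
#'
#' Number of histogram bins for a probability sample by one of five
#' standard rules: square root, Sturges, Rice, Scott, Freedman-Diaconis.
#' Results are rounded up and floored at 2 so the count is always a usable
#' integer.  Scott's and FD's rules divide by the sample spread; when that
#' spread is zero the square-root rule is used instead (with a warning).
#'
#' @param values probability vector (>= 2 values).
#' @param method one of `"sqrt"`, `"sturges"`, `"rice"`, `"scott"`, `"fd"`.
#' @return A single integer >= 2.
#' @examples
#' histogram_bin_count(runif(10000), "sqrt")     # 100
#' histogram_bin_count(runif(1024), "sturges")   # 11
#' @export
histogram_bin_count <- function(values,
                                method = c("sqrt", "sturges", "rice",
                                           "scott", "fd")) {
  method <- match.arg(method)
  check_prob_vector(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  nb <- switch(
    method,
    sqrt = sqrt(n),
    sturges = 1 + log2(n),
    rice = 2 * n^(1 / 3),
    scott = {
      h <- 3.5 * stats::sd(values) / n^(1 / 3)
      if (h == 0) {
        warning("zero standard deviation; falling back to sqrt rule")
        sqrt(n)
      } else (max(values) - min(values)) / h
    },
    fd = {
      h <- 2 * stats::IQR(values) / n^(1 / 3)
      if (h == 0) {
        warning("zero interquartile range; falling back to sqrt rule")
        sqrt(n)
      } else (max(values) - min(values)) / h
    }
  )
  max(2L, as.integer(ceiling(nb)))
}

#' Histogram-derived density on the shared evaluation grid
#'
#' Builds an equal-width histogram of `values` on \[0, 1\] with `n_bins`
#' bins, normalized so that bin density times bin width sums to 1, and
#' reports the density at the `n_bins` equispaced grid points used by
#' [beta_kernel_density()] (each grid point takes the density of the bin
#' containing it; bins are right-open, the last right-closed).
#'
#' @param values probability vector.
#' @param n_bins number of bins (>= 2).
#' @return A `density_grid` with an extra `bin_density` element holding the
#'   per-bin densities.
#' @export
histogram_density <- function(values, n_bins) {
  check_prob_vector(values)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  idx <- prob_bin_index(values, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  bin_density <- counts / (length(values) / n_bins)  # counts / (n * width)
  z <- seq(0, 1, length.out = n_bins)
  D <- bin_density[prob_bin_index(z, n_bins)]
  density_grid(z, D, NA_real_, n_bins, bin_density = bin_density)
}

# 1-D differential evolution (rand/1/bin), seeded, box-constrained.
# Small fixed budget; returns the best point seen.
de_optimize_1d <- function(fn, lower, upper, seed, np = 12, maxiter = 25,
                           f_weight = 0.8, cr = 0.9, tol = 1e-3) {
  withr::with_seed(seed, {
    pop <- stats::runif(np, lower, upper)
    pop[1] <- lower
    pop[2] <- upper
    cost <- vapply(pop, fn, numeric(1))
    for (iter in seq_len(maxiter)) {
      for (i in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), i), 3)
        trial <- pop[r[1]] + f_weight * (pop[r[2]] - pop[r[3]])
        if (stats::runif(1) > cr) trial <- pop[i]
        trial <- min(max(trial, lower), upper)
        tc <- fn(trial)
        if (tc <= cost[i]) {
          pop[i] <- trial
          cost[i] <- tc
        }
      }
      if (diff(range(pop)) < tol) break
    }
    list(par = pop[which.min(cost)], value = min(cost), iter = iter,
         converged = diff(range(pop)) < tol)
  })
}

#' MSE-optimal beta-kernel bandwidth
#'
#' Selects the bandwidth in \[0.01, 0.5\] minimizing the mean squared error
#' between the histogram-derived density and the beta-kernel density of
#' `values`, both evaluated on the same `n_bins`-point grid.  The search
#' uses a seeded differential-evolution style global optimizer (the
#' objective can be multimodal); if the population has not collapsed
#' within the iteration budget the best bandwidth seen is returned with a
#' warning.
#'
#' @param values probability vector.
#' @param n_bins number of grid points / histogram bins.
#' @param seed integer seed for the stochastic search.
#' @param metric `"mse"` (default) or `"js"` (Jensen-Shannon distance
#'   between the mass-normalized densities; available as an alternative,
#'   not used by the estimators' defaults).
#' @param control optional list overriding optimizer settings `np`,
#'   `maxiter`, `tol`.
#' @return A single bandwidth in \[0.01, 0.5\].
#' @export
estimate_bandwidth <- function(values, n_bins, seed = 1,
                               metric = c("mse", "js"), control = list()) {
  metric <- match.arg(metric)
  check_prob_vector(values)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  z <- seq(0, 1, length.out = n_bins)
  D_hist <- histogram_density(values, n_bins)$D
  S <- beta_kernel_core(values, z)
  err <- if (metric == "mse") {
    function(bw) mean((D_hist - beta_kernel_eval(S, z, bw))^2)
  } else {
    function(bw) {
      p <- D_hist / sum(D_hist)
      q <- beta_kernel_eval(S, z, bw)
      q <- q / sum(q)
      m <- (p + q) / 2
      kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
      sqrt((kl(p, m) + kl(q, m)) / 2)
    }
  }
  ctrl <- utils::modifyList(list(np = 12, maxiter = 25, tol = 1e-3), control)
  res <- de_optimize_1d(err, BW_RANGE[1], BW_RANGE[2], seed = seed,
                        np = ctrl$np, maxiter = ctrl$maxiter, tol = ctrl$tol)
  if (!res$converged) {
    warning("bandwidth search did not collapse; returning best bandwidth seen")
  }
  res$par
}
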