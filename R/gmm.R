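# Full-covariance Gaussian mixture model fitted by EM with ridge
# regularisation of the component covariances.  The regulariser keeps the
# BIC scan well defined at high dimension / large component counts, where
# unregularised full-covariance fits become singular.

# Per-component log density of a multivariate normal via Cholesky.
log_dmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  d <- ncol(x)
  xc <- sweep(x, 2, mu)
  q <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(q^2))
}

gmm_em <- function(x, G, resp, max_iter, tol, reg_covar) {
  n <- nrow(x); d <- ncol(x)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # M-step
    nk <- colSums(resp) + 10 * .Machine$double.eps
    w <- nk / n
    mu <- t(resp) %*% x / nk
    logdens <- matrix(0, n, G)
    sigma <- vector("list", G)
    for (g in seq_len(G)) {
      xc <- sweep(x, 2, mu[g, ])
      sg <- crossprod(xc * resp[, g], xc) / nk[g]
      diag(sg) <- diag(sg) + reg_covar
      sigma[[g]] <- sg
      logdens[, g] <- log_dmvnorm(x, mu[g, ], sg) + log(w[g])
    }
    # E-step
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    resp <- exp(logdens - lse)
    ll <- mean(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sigma = sigma, resp = resp,
       loglik = ll * n, iter = iter)
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' EM with k-means initialization (several seeded restarts, best
#' log-likelihood kept), full component covariances with a small ridge
#' (`reg_covar`) added to the diagonal, and BIC computed as
#' `-2 logLik + k log(n)` (smaller is better).
#'
#' @param x numeric matrix, observations in rows.
#' @param G number of mixture components (>= 1).
#' @param seed integer seed for the initializations.
#' @param max_iter maximum EM iterations (default 250).
#' @param tol convergence tolerance on the mean log-likelihood change.
#' @param n_init number of EM starts (each from its own k-means run); the
#'   default single start mirrors common GMM tooling and keeps BIC scans
#'   over many candidate counts affordable.
#' @param reg_covar ridge added to each covariance diagonal.
#' @param extra_assign optional assignment vector supplying one more EM
#'   start (used by [gmm_bic_scan()] for warm starts).
#' @return List with `weights`, `means`, `sigma`, `assignments`,
#'   `loglik`, `bic`, `G`, `n_params`.
#' @export
gmm_fit <- function(x, G, seed = 1, max_iter = 250, tol = 1e-3,
                    n_init = 1, reg_covar = 1e-6, extra_assign = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  stopifnot(G >= 1, n > G)
  best <- NULL
  if (G == 1) {
    resp <- matrix(1, n, 1)
    best <- gmm_em(x, 1, resp, max_iter = 1, tol = tol, reg_covar = reg_covar)
  } else {
    # initialize k-means on standardized columns: k-means is isotropic, so
    # unequal column scales (e.g. gain-scaled features) would otherwise
    # dominate the start; the EM itself runs on `x` as given
    sds <- apply(x, 2, stats::sd)
    x_init <- sweep(sweep(x, 2, colMeans(x)), 2, pmax(sds, 1e-12), "/")
    for (init in seq_len(n_init)) {
      km <- withr::with_seed(derive_seed(seed, init), {
        tryCatch(suppressWarnings(stats::kmeans(x_init, centers = G,
                                                nstart = 5, iter.max = 50)),
                 error = function(e) NULL)
      })
      assign0 <- if (is.null(km)) {
        withr::with_seed(derive_seed(seed, 100 + init),
                         sample(rep_len(seq_len(G), n)))
      } else km$cluster
      resp <- matrix(0, n, G)
      resp[cbind(seq_len(n), assign0)] <- 1
      fit <- gmm_em(x, G, resp, max_iter = max_iter, tol = tol,
                    reg_covar = reg_covar)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (!is.null(extra_assign) && length(unique(extra_assign)) == G) {
      resp <- matrix(0, n, G)
      resp[cbind(seq_len(n), extra_assign)] <- 1
      fit <- gmm_em(x, G, resp, max_iter = max_iter, tol = tol,
                    reg_covar = reg_covar)
      if (fit$loglik > best$loglik) best <- fit
    }
  }
  n_params <- (G - 1) + G * d + G * d * (d + 1) / 2
  best$assignments <- max.col(best$resp)
  best$G <- G
  best$n_params <- n_params
  best$bic <- -2 * best$loglik + n_params * log(n)
  best
}

#' BIC scan over candidate mixture component counts
#'
#' Fits [gmm_fit()] for each candidate count `1..max_c` and collects the
#' BIC values (smaller is better) plus the fitted models.  Each count
#' additionally warm-starts from the previous count's solution with its
#' largest component split in two, which keeps the BIC curve free of the
#' local-optimum bumps a cold k-means start can produce (a bump fakes a
#' knee for [choose_cluster_count()]).
#'
#' @param x numeric matrix.
#' @param max_c largest candidate component count.
#' @param seed integer seed.
#' @param ... passed to [gmm_fit()].
#' @return List with `bic` (numeric vector over counts `1..max_c`) and
#'   `fits` (list of fitted models).
#' @export
gmm_bic_scan <- function(x, max_c, seed = 1, ...) {
  max_c <- as.integer(max_c)
  stopifnot(max_c >= 2)
  fits <- vector("list", max_c)
  bic <- rep(NA_real_, max_c)
  for (G in seq_len(max_c)) {
    warm <- NULL
    if (G >= 2 && !is.null(fits[[G - 1]])) {
      warm <- split_largest_component(x, fits[[G - 1]]$assignments, G,
                                      seed = derive_seed(seed, 500 + G))
    }
    fits[[G]] <- gmm_fit(x, G, seed = derive_seed(seed, G),
                         extra_assign = warm, ...)
    bic[G] <- fits[[G]]$bic
  }
  list(bic = bic, fits = fits)
}

# Split the largest component of a (G-1)-component assignment in two via
# seeded 2-means, yielding a G-component warm start.
split_largest_component <- function(x, assignments, G, seed) {
  sizes <- tabulate(assignments)
  big <- which.max(sizes)
  idx <- which(assignments == big)
  if (length(idx) < 4) return(NULL)
  km <- withr::with_seed(seed, {
    tryCatch(suppressWarnings(stats::kmeans(x[idx, , drop = FALSE],
                                            centers = 2, nstart = 3)),
             error = function(e) NULL)
  })
  if (is.null(km)) return(NULL)
  out <- assignments
  out[idx[km$cluster == 2]] <- G
  out
}
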