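# PULSCAR: estimate the fraction alpha of positives among unlabeled
# examples under SCAR, from beta-kernel densities of classifier
# probabilities via a log mixture-gap objective and slope-change detection.

ALPHA_STEP <- 1e-4

# Restrict a density grid to a subset of its evaluation points.
within_grid <- function(grid, keep) {
  structure(list(z = grid$z[keep], D = grid$D[keep], bw = grid$bw,
                 n_bins = length(keep)),
            class = "density_grid")
}

check_grids_match <- function(Du, Dp) {
  stopifnot(inherits(Du, "density_grid"), inherits(Dp, "density_grid"))
  if (Du$n_bins != Dp$n_bins || !isTRUE(all.equal(Du$z, Dp$z))) {
    stop("'Du' and 'Dp' must be evaluated on identical grids", call. = FALSE)
  }
}

objective_epsilon <- function(Dp) {
  eps <- abs(min(Dp$D))
  if (eps == 0) 1e-10 else eps
}

#' Mixture-gap objective for alpha estimation
#'
#' The law of total probability gives `D_u = alpha * D_p + (1 - alpha) * D_n`,
#' so `D_u - alpha * D_p` must stay nonnegative for any admissible `alpha`.
#' The objective
#' \deqn{f(\alpha) = \log(|\min(D_u - \alpha D_p)| + \epsilon)}
#' tends to a sharp minimum near the largest admissible `alpha`, where the
#' scaled positive density first touches the unlabeled density.  The floor
#' `epsilon = |min(D_p)|` (or `1e-10` when `min(D_p) = 0`) keeps the
#' logarithm finite.
#'
#' @param alpha scalar or vector of mixture proportions in \[0, 1\].
#' @param Du,Dp `density_grid`s of the unlabeled and positive
#'   probabilities on identical grids.
#' @return Objective value(s), same length as `alpha`.
#' @examples
#' Du <- structure(list(z = c(0, 1), D = c(1, 1), n_bins = 2L),
#'                 class = "density_grid")
#' Dp <- structure(list(z = c(0, 1), D = c(2, 0.5), n_bins = 2L),
#'                 class = "density_grid")
#' pu_objective(0.2, Du, Dp)  # log(0.6 + 0.5)
#' @export
pu_objective <- function(alpha, Du, Dp) {
  check_grids_match(Du, Dp)
  stopifnot(all(alpha >= 0 & alpha <= 1))
  eps <- objective_epsilon(Dp)
  m <- rep(Inf, length(alpha))
  for (j in seq_along(Du$D)) {
    m <- pmin(m, Du$D[j] - alpha * Dp$D[j])
  }
  log(abs(m) + eps)
}

#' Upper bound on alpha from the density ratio
#'
#' The largest `alpha` keeping `D_u - alpha * D_p` nonnegative everywhere:
#' the minimum of `D_u / D_p` over grid points where `D_p > 0`, clipped to
#' \[0, 1\].  Serves as an independent diagnostic for the slope-change
#' estimate.
#'
#' @inheritParams pu_objective
#' @return A single value in \[0, 1\].
#' @export
alpha_max <- function(Du, Dp) {
  check_grids_match(Du, Dp)
  ok <- Dp$D != 0
  if (!any(ok)) stop("all positive-density bins are zero", call. = FALSE)
  min(1, max(0, min(Du$D[ok] / Dp$D[ok])))
}

# Candidate change points of the objective curve: |second difference| of f
# on the uniform alpha grid.  Index i of the returned vector corresponds
# to grid point alphas[i + 1], i.e. the point at which the slope changes;
# alpha = 0 can therefore never be returned.
slope_change_magnitude <- function(f) {
  abs(diff(diff(f)))
}

# Select the change-point index from the slope-change magnitudes g
# (g[i] belongs to grid point alphas[i + 1]).  Candidates are restricted
# to indices <= i_max, the admissible range where the implied negative
# density D_u - alpha * D_p stays above -epsilon: slope changes beyond it
# mark the gap's argmin switching bins in already-inadmissible territory,
# not a mixture touch point.
select_alpha_index <- function(g, mode, i_max = length(g)) {
  i_max <- max(1L, min(i_max, length(g)))
  ga <- g[seq_len(i_max)]
  if (mode == "max_slope_change") {
    return(which.max(ga))  # which.max: first (smallest-alpha) tie wins
  }
  # first_sharp_change: smallest-alpha local peak with magnitude >= 50%
  # of the admissible maximum
  n <- length(ga)
  left <- c(-Inf, ga[-n])
  right <- c(ga[-1], -Inf)
  peaks <- which(ga >= left & ga >= right & ga >= 0.5 * max(ga))
  peaks[1]
}

#' Estimate alpha directly from a pair of density grids
#'
#' The core of PULSCAR with the density-estimation stage stripped away:
#' evaluates the mixture-gap objective on the alpha grid `0, 1e-4, ..., 1`
#' for the supplied unlabeled / positive density pair and applies
#' slope-change selection.  Useful for diagnostics and for validating the
#' selection rule on analytically constructed mixtures.
#'
#' @inheritParams pu_objective
#' @param mode slope-change selection mode, see [pulscar()].
#' @return List with `alpha_hat`, `alpha_max` and `curve`.
#' @export
pulscar_from_densities <- function(Du, Dp,
                                   mode = c("max_slope_change",
                                            "first_sharp_change")) {
  mode <- match.arg(mode)
  alphas <- seq(0, 1, by = ALPHA_STEP)
  f <- pu_objective(alphas, Du, Dp)
  # admissible range: the implied negative density min(D_u - alpha * D_p)
  # may not dip below -min(D_u) — a violation smaller than the smallest
  # unlabeled density the grid resolves is within the estimate's
  # resolution, a larger one is a genuine constraint violation
  gap <- rep(Inf, length(alphas))
  for (j in seq_along(Du$D)) {
    gap <- pmin(gap, Du$D[j] - alphas * Dp$D[j])
  }
  adm <- which(gap >= -min(Du$D))
  i_adm <- if (length(adm)) max(adm) - 1L else length(alphas) - 2L
  i <- select_alpha_index(slope_change_magnitude(f), mode, i_max = i_adm)
  list(alpha_hat = alphas[i + 1L],
       alpha_max = alpha_max(Du, Dp),
       curve = list(alphas = alphas, f = f,
                    epsilon = objective_epsilon(Dp),
                    bw = Du$bw, n_bins = Du$n_bins))
}

#' Estimate alpha under SCAR from classifier probabilities (PULSCAR)
#'
#' Builds beta-kernel densities of the positive and unlabeled class-1
#' probabilities on a shared grid — with a single bandwidth estimated from
#' the pooled probabilities — evaluates the mixture-gap objective
#' [pu_objective()] on the alpha grid `0, 1e-4, ..., 1`, and returns the
#' grid point with the maximal absolute change in the objective's slope
#' (mode `"max_slope_change"`).  When the curve has several sharp changes,
#' mode `"first_sharp_change"` picks the smallest-alpha peak whose
#' magnitude is at least half the maximum.  In either mode candidates are
#' restricted to the admissible range where the gap
#' `min(D_u - alpha * D_p)` stays above `-epsilon` (the objective's own
#' outlier tolerance): beyond it the implied negative density is
#' materially negative, so a slope change out there marks the gap's
#' argmin switching bins, not a mixture touch point.
#'
#' @param pos_probs class-1 probabilities of labeled positives.
#' @param unl_probs class-1 probabilities of unlabeled examples.
#' @param n_bins number of grid points, or `"auto"` to apply `bin_method`
#'   to the pooled probabilities.
#' @param mode slope-change selection mode.
#' @param seed integer seed (bandwidth search).
#' @param bin_method bin-count rule used when `n_bins = "auto"`, see
#'   [histogram_bin_count()].
#' @param bw optional fixed bandwidth; skips bandwidth estimation.
#' @return An object of class `pulscar_fit`: list with `alpha_hat`,
#'   `curve` (list: `alphas`, `f`, `epsilon`, `bw`, `n_bins`),
#'   `alpha_max` (min-ratio diagnostic), `mode`, `seed`.
#' @examples
#' set.seed(7)
#' fit <- pulscar(rbeta(800, 8, 2), rbeta(800, 2, 8), n_bins = 30, seed = 1)
#' fit$alpha_hat
#' @export
pulscar <- function(pos_probs, unl_probs, n_bins = "auto",
                    mode = c("max_slope_change", "first_sharp_change"),
                    seed = 1, bin_method = "fd", bw = NULL) {
  mode <- match.arg(mode)
  check_prob_vector(pos_probs)
  check_prob_vector(unl_probs)
  pooled <- c(pos_probs, unl_probs)
  if (identical(n_bins, "auto")) {
    # cap at the sqrt rule of the scarcer sample: spread-based rules
    # (fd, scott) explode when the pooled scores concentrate in a spike,
    # and a grid finer than sqrt(min(|P|, |U|)) over-resolves whichever
    # of the two compared densities rests on fewer examples
    n_bins <- min(histogram_bin_count(pooled, bin_method),
                  as.integer(ceiling(sqrt(min(length(pos_probs),
                                              length(unl_probs))))))
  }
  n_bins <- as.integer(n_bins)
  if (length(unique(prob_bin_index(pos_probs, n_bins))) == 1 &&
      length(unique(prob_bin_index(unl_probs, n_bins))) == 1) {
    stop(paste0("degenerate densities: all mass concentrated in one bin ",
                "for both classes; classifier probabilities carry no signal"),
         call. = FALSE)
  }
  if (is.null(bw)) bw <- estimate_bandwidth(pooled, n_bins, seed = seed)
  Dp <- beta_kernel_density(pos_probs, bw, n_bins)
  Du <- beta_kernel_density(unl_probs, bw, n_bins)
  # the kernel analogue of the alpha_max clause "where D_p != 0": keep a
  # grid point only where each sample contributes at least one example's
  # worth of density mass per bin width — in empirically empty bins the
  # gap and the density ratio reflect kernel tails of a handful of
  # extreme scores, not the mixture
  supported <- Du$D * length(unl_probs) / n_bins >= 1 &
    Dp$D * length(pos_probs) / n_bins >= 1
  if (sum(supported) >= 3 && any(!supported)) {
    keep <- which(supported)
    core <- pulscar_from_densities(within_grid(Du, keep),
                                   within_grid(Dp, keep), mode = mode)
    core$curve$bw <- bw
    core$curve$n_bins <- n_bins
  } else {
    core <- pulscar_from_densities(Du, Dp, mode = mode)
  }
  structure(
    c(core, list(mode = mode, seed = as.integer(seed))),
    class = "pulscar_fit"
  )
}

#' @export
print.pulscar_fit <- function(x, ...) {
  cat(sprintf("PULSCAR alpha estimate: %.4f (alpha_max diagnostic %.4f)\n",
              x$alpha_hat, x$alpha_max))
  cat(sprintf("  bw = %.4f, n_bins = %d, mode = %s, seed = %d\n",
              x$curve$bw, x$curve$n_bins, x$mode, x$seed))
  invisible(x)
}

#' Full SCAR pipeline: out-of-fold probabilities, then PULSCAR
#'
#' Convenience wrapper running [cv_class1_probs()] on a PU dataset and
#' applying [pulscar()] to the resulting positive / unlabeled probability
#' split.
#'
#' @param data a [pu_dataset()].
#' @param folds CV folds for the probability model.
#' @param weight_positives apply the `|U|/|P|` class weight.
#' @param classifier classifier specification, see [xgb_classifier()].
#' @param ... passed to [pulscar()].
#' @param seed integer master seed.
#' @return A `pulscar_fit` with an extra element `scored` (the
#'   [cv_class1_probs()] result).
#' @export
estimate_alpha_scar <- function(data, folds = 5, weight_positives = TRUE,
                                classifier = xgb_classifier(), seed = 1, ...) {
  scored <- cv_class1_probs(data, folds = folds,
                            weight_positives = weight_positives,
                            seed = seed, classifier = classifier)
  fit <- pulscar(scored$p[data$s == 1L], scored$p[data$s == 0L],
                 seed = derive_seed(seed, 101L), ...)
  fit$scored <- scored
  fit
}
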