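# PULSNAR: estimate alpha under SNAR by clustering labeled positives on
# gain-scaled important features, running PULSCAR per cluster against all
# unlabeled examples, and summing the per-cluster estimates.

#' Scale positive-example features by their gain importance
#'
#' Restricts to the important features of the probability model and
#' multiplies each kept column by its gain score, so that features that
#' matter for separating labeled from unlabeled examples dominate the
#' clustering geometry.  "Important" defaults to carrying at least the
#' average gain share (`gain >= mean(gains)`): a deep boosted ensemble
#' touches almost every feature at least once, so a bare `gain > 0` filter
#' keeps pure-noise columns whose only effect is to blur the clustering
#' and inflate the mixture's BIC penalty.  Set `threshold = "positive"`
#' for the literal nonzero-gain filter.
#'
#' @param pos_features feature matrix of the labeled positives.
#' @param gains named nonnegative gain vector from [gain_importances()].
#' @param threshold `"mean"` (default) keeps `gain >= mean(gains)`;
#'   `"positive"` keeps `gain > 0`.
#' @return The scaled matrix restricted to the important columns.
#' @export
scale_by_gain <- function(pos_features, gains,
                          threshold = c("mean", "positive")) {
  threshold <- match.arg(threshold)
  pos_features <- as.matrix(pos_features)
  stopifnot(length(gains) == ncol(pos_features))
  if (!any(gains > 0)) {
    stop("no feature has gain > 0; clustering is impossible", call. = FALSE)
  }
  keep <- if (threshold == "mean") {
    which(gains >= mean(gains))
  } else {
    which(gains > 0)
  }
  sweep(pos_features[, keep, drop = FALSE], 2, gains[keep], `*`)
}

#' Pick the cluster count at the knee of a BIC curve
#'
#' Given BIC values for candidate counts `1..max_c` (smaller is better),
#' returns the count at the sharpest concave knee: for each interior
#' candidate the angle between the segments to its two neighbors is
#' computed in (count, min-max-normalized BIC) space, and the candidate
#' with the maximal bend (smallest interior angle) among those where the
#' curve is convex (flattening) wins; ties go to the smaller count.  If no
#' interior point forms a concave knee — e.g. an exactly linear curve —
#' the fallback is 2.  Because a knee needs three consecutive points the
#' procedure can never return 1 cluster.
#'
#' @param bic numeric BIC vector over candidate counts `1, 2, ...`
#'   (length >= 3); `NA` entries (failed fits) are only tolerated at the
#'   tail.
#' @return An integer cluster count >= 2.
#' @examples
#' choose_cluster_count(c(100, 60, 40, 38, 37, 36))  # 3
#' choose_cluster_count(c(100, 90, 80, 70, 60))      # 2 (linear: fallback)
#' @export
choose_cluster_count <- function(bic) {
  ok <- is.finite(bic)
  if (any(!ok)) bic <- bic[seq_len(which(!ok)[1] - 1)]
  m <- length(bic)
  if (m < 3) stop("need BIC values for at least 3 candidate counts",
                  call. = FALSE)
  rng <- max(bic) - min(bic)
  b <- if (rng > 0) (bic - min(bic)) / rng else rep(0, m)
  best <- NA_integer_
  best_angle <- Inf
  for (i in 2:(m - 1)) {
    if (b[i - 1] + b[i + 1] - 2 * b[i] <= 1e-12) next  # not a concave knee
    u <- c(-1, b[i - 1] - b[i])
    v <- c(1, b[i + 1] - b[i])
    ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    if (ang < best_angle - 1e-12) {
      best_angle <- ang
      best <- i
    }
  }
  if (is.na(best)) 2L else as.integer(best)
}

# Merge clusters smaller than `min_size` into the nearest (centroid
# distance in scaled-feature space) larger cluster.
merge_small_clusters <- function(assignments, scaled, min_size) {
  repeat {
    sizes <- table(assignments)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0 || length(sizes) <= 1) break
    j <- small[which.min(sizes[small])]
    centroids <- do.call(rbind, lapply(names(sizes), function(g) {
      colMeans(scaled[assignments == g, , drop = FALSE])
    }))
    rownames(centroids) <- names(sizes)
    others <- setdiff(names(sizes), j)
    dists <- vapply(others, function(g) {
      sum((centroids[g, ] - centroids[j, ])^2)
    }, numeric(1))
    target <- others[which.min(dists)]
    warning(sprintf("merging cluster %s (%d members < %d) into cluster %s",
                    j, sizes[[j]], min_size, target))
    assignments[assignments == as.integer(j)] <- as.integer(target)
  }
  match(assignments, sort(unique(assignments)))
}

#' Estimate alpha under SNAR (PULSNAR)
#'
#' Labeling that depends on positive subtype (SNAR) breaks the single
#' scaling factor linking the positive and unlabeled densities: the rarest
#' labeled subtype drives a PULSCAR underestimate.  PULSNAR therefore
#' divides the labeled positives into clusters of (approximately) uniform
#' selection bias and solves one SCAR subproblem per cluster:
#'
#' 1. out-of-fold probabilities and feature gains on the full PU data;
#' 2. labeled positives clustered on gain-scaled important features with a
#'    seeded full-covariance Gaussian mixture (EM, max 250 iterations),
#'    candidate counts `1..max_c` scored by BIC and the count chosen at
#'    the BIC knee ([choose_cluster_count()]);
#' 3. for each cluster, [pulscar()] on (cluster positives) vs (all
#'    unlabeled), each run a full pipeline with its own out-of-fold
#'    probabilities, bin count and bandwidth;
#' 4. `alpha_total` is the sum of the per-cluster estimates.
#'
#' Clusters below `min_cluster_size` are merged into their nearest cluster
#' (with a warning) so that the sum over clusters stays meaningful.  The
#' raw sum is reported even when it exceeds 1 (flagged when printing).
#'
#' @param data a [pu_dataset()].
#' @param n_bins grid size for the per-cluster PULSCAR runs, or `"auto"`.
#' @param max_c largest candidate cluster count (default 25).
#' @param folds CV folds for probability models.
#' @param seed integer master seed.
#' @param min_cluster_size smallest allowed cluster (default 20).
#' @param weight_positives apply the `|U|/|P|` class weight in each run.
#' @param mode slope-change selection mode for the per-cluster PULSCAR.
#' @param classifier classifier specification, see [xgb_classifier()].
#' @param n_init,reg_covar Gaussian-mixture fitting controls, see
#'   [gmm_fit()].
#' @return An object of class `pulsnar_fit`: list with
#'   `per_cluster_alpha`, `alpha_total`, `cluster_model` (list:
#'   `assignments`, `bic`, `chosen_c`, `seed`), `per_cluster` (per-cluster
#'   fits, each with the cluster's positive / unlabeled probabilities),
#'   `gains`, `scored` (full-data out-of-fold probabilities), `seed`.
#' @export
pulsnar <- function(data, n_bins = "auto", max_c = 25, folds = 5, seed = 1,
                    min_cluster_size = 20, weight_positives = TRUE,
                    mode = "max_slope_change", classifier = xgb_classifier(),
                    n_init = 1, reg_covar = 1e-6) {
  stopifnot(inherits(data, "pu_dataset"), max_c >= 2)
  scored <- cv_class1_probs(data, folds = folds,
                            weight_positives = weight_positives,
                            seed = seed, classifier = classifier)
  gains <- gain_importances(data, seed = derive_seed(seed, 7L),
                            classifier = classifier)
  pos_idx <- which(data$s == 1L)
  unl_idx <- which(data$s == 0L)
  scaled <- scale_by_gain(data$features[pos_idx, , drop = FALSE], gains)
  max_c_eff <- min(max_c, length(pos_idx) - 1L)
  scan <- gmm_bic_scan(scaled, max_c_eff, seed = derive_seed(seed, 11L),
                       n_init = n_init, reg_covar = reg_covar)
  chosen_c <- choose_cluster_count(scan$bic)
  assignments <- scan$fits[[chosen_c]]$assignments
  assignments <- merge_small_clusters(assignments, scaled, min_cluster_size)
  cluster_ids <- sort(unique(assignments))
  per_cluster <- vector("list", length(cluster_ids))
  for (j in seq_along(cluster_ids)) {
    rows <- c(pos_idx[assignments == cluster_ids[j]], unl_idx)
    sub <- pu_dataset(data$features[rows, , drop = FALSE],
                      s = data$s[rows])
    seed_j <- derive_seed(seed, 1000L + j)
    sc_j <- cv_class1_probs(sub, folds = folds,
                            weight_positives = weight_positives,
                            seed = seed_j, classifier = classifier)
    fit_j <- pulscar(sc_j$p[sub$s == 1L], sc_j$p[sub$s == 0L],
                     n_bins = n_bins, mode = mode,
                     seed = derive_seed(seed_j, 101L))
    fit_j$p_pos <- sc_j$p[sub$s == 1L]
    fit_j$p_unl <- sc_j$p[sub$s == 0L]
    per_cluster[[j]] <- fit_j
  }
  per_cluster_alpha <- vapply(per_cluster, `[[`, numeric(1), "alpha_hat")
  structure(
    list(per_cluster_alpha = per_cluster_alpha,
         alpha_total = sum(per_cluster_alpha),
         cluster_model = list(assignments = assignments,
                              bic = scan$bic,
                              chosen_c = chosen_c,
                              n_clusters_final = length(cluster_ids),
                              scaled_features = scaled,
                              seed = as.integer(seed)),
         per_cluster = per_cluster,
         gains = gains,
         scored = scored,
         seed = as.integer(seed)),
    class = "pulsnar_fit"
  )
}

#' @rdname pulsnar
#' @param ... passed to [pulsnar()].
#' @export
estimate_alpha_snar <- function(data, ...) pulsnar(data, ...)

#' @export
print.pulsnar_fit <- function(x, ...) {
  cat(sprintf("PULSNAR alpha estimate: %.4f over %d clusters (BIC knee at %d)\n",
              x$alpha_total, length(x$per_cluster_alpha),
              x$cluster_model$chosen_c))
  if (x$alpha_total > 1) {
    cat("  note: raw per-cluster sum exceeds 1 (clip for reporting)\n")
  }
  cat("  per-cluster alpha:",
      paste(sprintf("%.4f", x$per_cluster_alpha), collapse = ", "), "\n")
  invisible(x)
}
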