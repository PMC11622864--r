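# Probability calibration against an alpha estimate: histogram-matched
# label flipping among unlabeled examples, isotonic / sigmoid fitting, and
# per-cluster probability combination for the SNAR path.

#' Flip unlabeled labels to match the positive probability histogram
#'
#' Marks `round(alpha * |U|)` unlabeled examples as positive so that the
#' flipped examples reproduce the probability histogram of the labeled
#' positives: the per-bin flip targets are `alpha * |U|` times the
#' positive histogram's bin masses (integerized by largest-remainder
#' apportionment so the total is exact).  Bins are processed from the
#' highest-probability bin downward; within a bin the flipped examples
#' are chosen uniformly at random (seeded), and any shortfall in an
#' over-demanded bin carries to the next lower bin.  Should demand remain
#' after the lowest bin, the leftover flips go to the unflipped unlabeled
#' examples with the highest probabilities, so the flip total is always
#' exact.
#'
#' @param pos_probs class-1 probabilities of labeled positives.
#' @param unl_probs class-1 probabilities of unlabeled examples.
#' @param alpha fraction of unlabeled examples to flip, in \[0, 1\].
#' @param n_bins number of equispaced bins over \[0, 1\] (default 100).
#' @param seed integer seed for the within-bin sampling.
#' @return List with `flipped` (0/1 vector over the unlabeled examples,
#'   1 = flipped) and `per_bin_flip_counts` (integer vector, bin 1 =
#'   lowest probabilities).
#' @export
flip_by_positive_histogram <- function(pos_probs, unl_probs, alpha,
                                       n_bins = 100, seed = 1) {
  check_prob_vector(pos_probs)
  check_prob_vector(unl_probs)
  check_alpha(alpha)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  n_u <- length(unl_probs)
  total <- round(alpha * n_u)
  if (total > n_u) stop("cannot flip more examples than exist", call. = FALSE)
  flipped <- integer(n_u)
  per_bin <- integer(n_bins)
  if (total > 0) {
    pos_mass <- tabulate(prob_bin_index(pos_probs, n_bins), nbins = n_bins) /
      length(pos_probs)
    targets <- largest_remainder(pos_mass, total)
    bins_u <- prob_bin_index(unl_probs, n_bins)
    carry <- 0L
    withr::with_seed(seed, {
      for (k in rev(seq_len(n_bins))) {
        need <- targets[k] + carry
        avail <- which(bins_u == k & flipped == 0L)
        take <- min(need, length(avail))
        if (take > 0) {
          sel <- if (length(avail) == 1) avail else sample(avail, take)
          flipped[sel[seq_len(take)]] <- 1L
          per_bin[k] <- take
        }
        carry <- need - take
      }
      if (carry > 0) {  # demand outlived the bins: place by highest prob
        left <- which(flipped == 0L)
        sel <- left[order(-unl_probs[left])][seq_len(carry)]
        flipped[sel] <- 1L
        extra <- tabulate(bins_u[sel], nbins = n_bins)
        per_bin <- per_bin + extra
      }
    })
  }
  list(flipped = flipped, per_bin_flip_counts = per_bin)
}

#' Fit a monotone probability calibrator
#'
#' Maps classifier scores to calibrated probabilities by isotonic
#' regression (monotone least squares; preserves the label mean on its
#' training points) or a sigmoid (logistic regression on the score).  If
#' the labels contain a single class the constant class rate is returned
#' with a warning.
#'
#' @param probs classifier scores in \[0, 1\].
#' @param labels 0/1 labels, same length.
#' @param method `"isotonic"` or `"sigmoid"`.
#' @return Calibrated probabilities on the training points, with an
#'   attribute `"predict"` holding a vectorized function for new scores.
#' @export
fit_calibrator <- function(probs, labels, method = c("isotonic", "sigmoid")) {
  method <- match.arg(method)
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) == 1) {
    warning("single-class labels: returning the constant class rate")
    rate <- mean(labels)
    out <- rep(rate, length(probs))
    attr(out, "predict") <- function(x) rep(rate, length(x))
    return(out)
  }
  if (method == "isotonic") {
    ord <- order(probs)
    iso <- stats::isoreg(probs[ord], labels[ord])
    fitted <- numeric(length(probs))
    fitted[ord] <- iso$yf
    # step interpolation for unseen scores, clamped at the ends
    ux <- probs[ord]
    dedup <- !duplicated(ux, fromLast = TRUE)  # at ties keep last fitted value
    fun <- stats::approxfun(ux[dedup], iso$yf[dedup], method = "constant",
                            rule = 2, f = 0)
    out <- pmin(pmax(fitted, 0), 1)
    attr(out, "predict") <- function(x) pmin(pmax(fun(x), 0), 1)
    out
  } else {
    df <- data.frame(p = probs, y = labels)
    fit <- suppressWarnings(stats::glm(y ~ p, family = stats::binomial(),
                                       data = df))
    out <- as.numeric(stats::predict(fit, type = "response"))
    attr(out, "predict") <- function(x) {
      as.numeric(stats::predict(fit, newdata = data.frame(p = x),
                                type = "response"))
    }
    out
  }
}

#' Combine a cluster's worth of probabilities for one example
#'
#' An unlabeled example in the SNAR path receives one calibrated
#' probability per cluster; the probability that it is a positive of any
#' subtype is one minus the probability it belongs to none:
#' `1 - prod(1 - p_j)`.  The result is bounded by `[max(p_j), 1]` and is
#' invariant to the cluster order.
#'
#' @param p numeric vector of per-cluster probabilities in \[0, 1\].
#' @return A single combined probability.
#' @examples
#' combine_cluster_probabilities(c(0.5, 0.5))  # 0.75
#' @export
combine_cluster_probabilities <- function(p) {
  if (length(p) == 0) stop("empty probability list", call. = FALSE)
  check_prob_vector(p)
  1 - prod(1 - p)
}

#' Calibrate classifier probabilities against an alpha estimate
#'
#' Implements the flip-then-fit calibration: `round(alpha * |U|)`
#' unlabeled labels are flipped to 1 so as to match the labeled-positive
#' probability histogram ([flip_by_positive_histogram()]), then a monotone
#' calibrator ([fit_calibrator()]) is fit on the classifier scores versus
#' the updated labels.  With `scope = "PU"` the fit uses positives and
#' unlabeled together (calibrated sums approximate `|P| + alpha|U|`); with
#' `scope = "U"` only the unlabeled examples (calibrated sums approximate
#' `alpha|U|`).
#'
#' @param data a [pu_dataset()].
#' @param scored a `scored_pu` from [cv_class1_probs()] aligned to `data`.
#' @param alpha the alpha estimate to calibrate against.
#' @param method `"isotonic"` or `"sigmoid"`.
#' @param scope `"PU"` or `"U"`.
#' @param n_bins histogram bins for the flip step (default 100).
#' @param seed integer seed.
#' @return An object of class `pu_calibration`: list with
#'   `flipped_labels` (full-length updated labels; positives keep 1),
#'   `calibrated` (full-length; `NA` for positives when `scope = "U"`),
#'   `method`, `scope`, `per_bin_flip_counts`, `n_flipped`, `seed`.
#' @export
calibrate_pu <- function(data, scored, alpha, method = c("isotonic", "sigmoid"),
                         scope = c("PU", "U"), n_bins = 100, seed = 1) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  stopifnot(inherits(data, "pu_dataset"),
            length(scored$p) == length(data$s))
  check_alpha(alpha)
  pos <- data$s == 1L
  p_p <- scored$p[pos]
  p_u <- scored$p[!pos]
  fl <- flip_by_positive_histogram(p_p, p_u, alpha, n_bins = n_bins,
                                   seed = seed)
  s_hat <- data$s
  s_hat[!pos] <- fl$flipped
  calibrated <- rep(NA_real_, length(data$s))
  if (scope == "PU") {
    calibrated[c(which(pos), which(!pos))] <-
      fit_calibrator(c(p_p, p_u), c(rep(1L, sum(pos)), fl$flipped), method)
  } else {
    calibrated[!pos] <- fit_calibrator(p_u, fl$flipped, method)
  }
  structure(
    list(flipped_labels = s_hat, calibrated = calibrated, method = method,
         scope = scope, per_bin_flip_counts = fl$per_bin_flip_counts,
         n_flipped = sum(fl$flipped), seed = as.integer(seed)),
    class = "pu_calibration"
  )
}

#' @export
print.pu_calibration <- function(x, ...) {
  cat(sprintf("PU calibration (%s, scope %s): %d unlabeled labels flipped; sum(calibrated) = %.2f\n",
              x$method, x$scope, x$n_flipped,
              sum(x$calibrated, na.rm = TRUE)))
  invisible(x)
}

#' Calibrate a PULSNAR fit cluster by cluster and combine
#'
#' Runs the flip-then-fit calibration once per cluster — using that
#' cluster's own out-of-fold probabilities and alpha — and combines the
#' resulting per-cluster unlabeled probabilities with
#' [combine_cluster_probabilities()].  A labeled positive keeps the
#' calibrated value from its own cluster's calibrator; the product
#' combination applies to unlabeled examples only.
#'
#' @param data the [pu_dataset()] the fit was computed on.
#' @param fit a `pulsnar_fit` from [pulsnar()].
#' @param method `"isotonic"` or `"sigmoid"`.
#' @param scope `"PU"` (fit each cluster's calibrator on that cluster's
#'   positives plus all unlabeled) or `"U"` (unlabeled only).
#' @param n_bins histogram bins for the flip step.
#' @param seed integer seed.
#' @return List with `calibrated_unl` (combined probabilities over
#'   unlabeled rows), `calibrated_pos` (per labeled positive, own
#'   cluster; `NA` when `scope = "U"`), `per_cluster` (matrix of
#'   unlabeled probabilities, one column per cluster), `alpha_total`.
#' @export
calibrate_snar <- function(data, fit, method = c("isotonic", "sigmoid"),
                           scope = c("U", "PU"), n_bins = 100, seed = 1) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  stopifnot(inherits(fit, "pulsnar_fit"))
  n_u <- sum(data$s == 0L)
  assignments <- fit$cluster_model$assignments
  k <- length(fit$per_cluster)
  per_cluster <- matrix(NA_real_, n_u, k)
  calibrated_pos <- rep(NA_real_, sum(data$s == 1L))
  for (j in seq_len(k)) {
    cl <- fit$per_cluster[[j]]
    alpha_j <- min(1, cl$alpha_hat)
    fl <- flip_by_positive_histogram(cl$p_pos, cl$p_unl, alpha_j,
                                     n_bins = n_bins,
                                     seed = derive_seed(seed, j))
    if (scope == "PU") {
      cal <- fit_calibrator(c(cl$p_pos, cl$p_unl),
                            c(rep(1L, length(cl$p_pos)), fl$flipped), method)
      calibrated_pos[assignments == j] <- cal[seq_along(cl$p_pos)]
      per_cluster[, j] <- cal[-seq_along(cl$p_pos)]
    } else {
      per_cluster[, j] <- fit_calibrator(cl$p_unl, fl$flipped, method)
    }
  }
  calibrated_unl <- 1 - apply(1 - per_cluster, 1, prod)
  list(calibrated_unl = calibrated_unl, calibrated_pos = calibrated_pos,
       per_cluster = per_cluster, alpha_total = fit$alpha_total)
}
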