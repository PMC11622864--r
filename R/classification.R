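# Alpha-guided relabeling and retraining, and the six-metric evaluation
# report (accuracy, AUC-ROC, Brier score, F1, MCC, average precision).

#' Relabel the top alpha-fraction of unlabeled examples as positive
#'
#' Flags exactly `round(alpha * |U|)` unlabeled examples — those with the
#' highest calibrated probabilities — as probable positives.  Ties at the
#' cutoff are broken by original row order (stable).
#'
#' @param calibrated_unl calibrated probabilities of the unlabeled
#'   examples.
#' @param alpha fraction to relabel, in \[0, 1\].
#' @return 0/1 vector over the unlabeled examples.
#' @examples
#' relabel_top_alpha(c(0.9, 0.8, 0.1, 0.2), 0.5)  # 1 1 0 0
#' @export
relabel_top_alpha <- function(calibrated_unl, alpha) {
  check_prob_vector(calibrated_unl, allow_empty = TRUE)
  check_alpha(alpha)
  n <- length(calibrated_unl)
  k <- round(alpha * n)
  labels <- integer(n)
  if (k > 0) {
    ord <- order(-calibrated_unl, seq_len(n))  # stable: earlier rows win ties
    labels[ord[seq_len(k)]] <- 1L
  }
  labels
}

#' Six-metric classification report
#'
#' Computes accuracy, AUC-ROC, Brier score, F1, Matthews correlation
#' coefficient and average precision of probabilities against ground
#' truth.  Thresholded metrics (accuracy, F1, MCC) use `threshold`
#' (default 0.5).  With single-class truth, AUC-ROC and MCC are undefined
#' and reported as `NA` with a warning.
#'
#' @param probs class-1 probabilities.
#' @param y_true 0/1 ground truth, same length.
#' @param threshold decision threshold for the thresholded metrics.
#' @return An object of class `pu_metrics`: list with `accuracy`,
#'   `auc_roc`, `brier`, `f1`, `mcc`, `aps`, `threshold`.
#' @examples
#' evaluate_metrics(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
#' @export
evaluate_metrics <- function(probs, y_true, threshold = 0.5) {
  check_prob_vector(probs)
  y_true <- as.integer(y_true)
  stopifnot(length(probs) == length(y_true), all(y_true %in% c(0L, 1L)))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  accuracy <- (tp + tn) / length(y_true)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  brier <- mean((probs - y_true)^2)
  single_class <- length(unique(y_true)) == 1
  if (single_class) {
    warning("y_true contains a single class: auc_roc and mcc are undefined")
    auc_roc <- NA_real_
    mcc <- NA_real_
    aps <- NA_real_
  } else {
    auc_roc <- as.numeric(pROC::auc(y_true, probs, direction = "<",
                                    quiet = TRUE))
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
    # average precision: mean of precision at each true positive, in
    # decreasing-score order (the step-integral of the PR curve)
    ord <- order(-probs, seq_along(probs))
    ys <- y_true[ord]
    prec <- cumsum(ys) / seq_along(ys)
    aps <- sum(prec * ys) / sum(ys)
  }
  structure(list(accuracy = accuracy, auc_roc = auc_roc, brier = brier,
                 f1 = f1, mcc = mcc, aps = aps, threshold = threshold),
            class = "pu_metrics")
}

#' @export
print.pu_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | auc_roc %.4f | brier %.4f | ",
                     "f1 %.4f | mcc %.4f | aps %.4f (threshold %.2f)\n"),
              x$accuracy, x$auc_roc, x$brier, x$f1, x$mcc, x$aps,
              x$threshold))
  invisible(x)
}

#' Improve classification with an alpha estimate and evaluate
#'
#' The alpha-guided retraining loop: calibrate the out-of-fold
#' probabilities of the unlabeled examples (scope `"U"`), flip the top
#' `round(alpha * |U|)` calibrated unlabeled examples to probable
#' positives, retrain the classifier with cross-validation on the updated
#' labels, and score the second classifier's probabilities against the
#' ground truth.  The baseline report — the same classifier on the raw
#' assigned labels — is returned alongside for comparison.
#'
#' For SNAR data pass the combined per-cluster calibrated probabilities
#' (from [calibrate_snar()]) as `calibrated_unl` together with the summed
#' alpha.
#'
#' @param data a [pu_dataset()] carrying `y_true`.
#' @param alpha the alpha estimate guiding the relabeling.
#' @param calibrated_unl optional pre-computed calibrated probabilities of
#'   the unlabeled rows; computed via [calibrate_pu()] when `NULL`.
#' @param method calibration method.
#' @param n_bins histogram bins for the flip step.
#' @param folds CV folds.
#' @param seed integer master seed.
#' @param threshold decision threshold for the thresholded metrics.
#' @param weight_positives apply the imbalance weight during training.
#' @param classifier classifier specification, see [xgb_classifier()].
#' @return An object of class `pu_class_report`: list with `with_pu` and
#'   `without_pu` (both [evaluate_metrics()] reports), `alpha`,
#'   `n_relabel`, `threshold`.
#' @export
improve_and_evaluate <- function(data, alpha, calibrated_unl = NULL,
                                 method = "isotonic", n_bins = 100,
                                 folds = 5, seed = 1, threshold = 0.5,
                                 weight_positives = TRUE,
                                 classifier = xgb_classifier()) {
  stopifnot(inherits(data, "pu_dataset"))
  if (is.null(data$y_true)) {
    stop("'data' must carry y_true for evaluation", call. = FALSE)
  }
  check_alpha(alpha)
  scored <- cv_class1_probs(data, folds = folds,
                            weight_positives = weight_positives,
                            seed = seed, classifier = classifier)
  if (is.null(calibrated_unl)) {
    cal <- calibrate_pu(data, scored, alpha, method = method, scope = "U",
                        n_bins = n_bins, seed = derive_seed(seed, 31L))
    calibrated_unl <- cal$calibrated[data$s == 0L]
  }
  s_hat <- data$s
  s_hat[data$s == 0L] <- relabel_top_alpha(calibrated_unl, alpha)
  retrain <- pu_dataset(data$features, s_hat)
  scored2 <- cv_class1_probs(retrain, folds = folds,
                             weight_positives = weight_positives,
                             seed = seed, classifier = classifier)
  structure(
    list(with_pu = evaluate_metrics(scored2$p, data$y_true, threshold),
         without_pu = evaluate_metrics(scored$p, data$y_true, threshold),
         alpha = alpha, n_relabel = sum(s_hat) - sum(data$s),
         threshold = threshold),
    class = "pu_class_report"
  )
}

#' @export
print.pu_class_report <- function(x, ...) {
  cat(sprintf("alpha = %.4f, %d unlabeled examples relabeled as probable positives\n",
              x$alpha, x$n_relabel))
  cat("with PU step:    "); print(x$with_pu)
  cat("without PU step: "); print(x$without_pu)
  invisible(x)
}
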