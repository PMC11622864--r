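#' Construct a positive-unlabeled (PU) dataset
#'
#' A PU dataset is a numeric feature matrix plus an assigned-label vector
#' `s` where `s = 1` marks a labeled positive and `s = 0` an unlabeled
#' example (a mix of hidden positives and negatives).  Optionally carries
#' the ground truth `y_true` for evaluation and the hidden positive
#' subclass id (`0` for negatives), as produced by the synthetic
#' generators.
#'
#' The PU assumption that only true positives are ever labeled is
#' enforced: when `y_true` is given, every `s = 1` row must have
#' `y_true = 1`.
#'
#' @param features numeric matrix (or data frame of numerics),
#'   `n_examples x n_features`.
#' @param s assigned labels, 0/1 vector; 1 = labeled positive.
#' @param y_true optional 0/1 ground-truth labels.
#' @param subclass optional integer vector of hidden positive subtypes
#'   (0 for negatives).
#' @param feature_names optional character vector of column names.
#' @return An object of class `pu_dataset`: a list with elements
#'   `features`, `s`, `y_true`, `subclass`, `feature_names`.
#' @examples
#' d <- pu_dataset(matrix(rnorm(20), 10, 2), s = rep(c(1, 0), 5))
#' d
#' @export
pu_dataset <- function(features, s, y_true = NULL, subclass = NULL,
                       feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features) || any(!is.finite(features))) {
    stop("'features' contains non-finite values", call. = FALSE)
  }
  s <- as.integer(s)
  if (length(s) != nrow(features)) {
    stop("length(s) must equal nrow(features)", call. = FALSE)
  }
  if (!all(s %in% c(0L, 1L))) {
    stop("'s' must contain only 0 (unlabeled) and 1 (labeled positive)",
         call. = FALSE)
  }
  if (sum(s == 1L) < 1 || sum(s == 0L) < 1) {
    stop("need at least one labeled positive and one unlabeled example",
         call. = FALSE)
  }
  if (!is.null(y_true)) {
    y_true <- as.integer(y_true)
    stopifnot(length(y_true) == length(s), all(y_true %in% c(0L, 1L)))
    if (any(s == 1L & y_true != 1L)) {
      stop("PU assumption violated: a labeled (s = 1) example has y_true = 0",
           call. = FALSE)
    }
  }
  if (!is.null(subclass)) {
    subclass <- as.integer(subclass)
    stopifnot(length(subclass) == length(s))
  }
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) {
    feature_names <- paste0("x", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, s = s, y_true = y_true,
         subclass = subclass, feature_names = feature_names),
    class = "pu_dataset"
  )
}

#' @export
print.pu_dataset <- function(x, ...) {
  cat(sprintf("PU dataset: %d examples x %d features | labeled positives: %d, unlabeled: %d\n",
              nrow(x$features), ncol(x$features), sum(x$s == 1), sum(x$s == 0)))
  if (!is.null(x$y_true)) {
    cat(sprintf("  ground truth present: %d true positives (%d hidden among unlabeled)\n",
                sum(x$y_true == 1), sum(x$y_true == 1 & x$s == 0)))
  }
  if (!is.null(x$subclass)) {
    cat(sprintf("  positive subclasses: %s\n",
                paste(sort(unique(x$subclass[x$subclass > 0])), collapse = ", ")))
  }
  invisible(x)
}

#' Read a PU dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header row.  One column holds the assigned
#' label `s`; optional columns hold `y_true` and the positive subclass.
#' All remaining numeric columns become features.
#'
#' @param path file path.
#' @param s_col name of the assigned-label column (default `"s"`).
#' @param y_col optional name of the ground-truth column.
#' @param subclass_col optional name of the subclass column.
#' @param sep field separator; `","` for CSV, `"\t"` for TSV.
#' @return A [pu_dataset()].
#' @export
read_pu_csv <- function(path, s_col = "s", y_col = NULL, subclass_col = NULL,
                        sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!s_col %in% names(df)) {
    stop(sprintf("column '%s' not found in %s", s_col, path), call. = FALSE)
  }
  s <- df[[s_col]]
  if (!all(s %in% c(0, 1))) {
    stop(sprintf("column '%s' must be 0/1", s_col), call. = FALSE)
  }
  y_true <- if (!is.null(y_col)) df[[y_col]] else NULL
  subclass <- if (!is.null(subclass_col)) df[[subclass_col]] else NULL
  drop <- c(s_col, y_col, subclass_col)
  feat_df <- df[, setdiff(names(df), drop), drop = FALSE]
  feat_df <- feat_df[, vapply(feat_df, is.numeric, logical(1)), drop = FALSE]
  if (ncol(feat_df) == 0) stop("no numeric feature columns found", call. = FALSE)
  pu_dataset(as.matrix(feat_df), s, y_true = y_true, subclass = subclass,
             feature_names = names(feat_df))
}

#' Write a PU dataset to CSV
#'
#' Inverse of [read_pu_csv()]: writes features plus `s` and, when present,
#' `y_true` and `subclass` columns.
#'
#' @param data a [pu_dataset()].
#' @param path output file path.
#' @export
write_pu_csv <- function(data, path) {
  df <- as.data.frame(data$features)
  df$s <- data$s
  if (!is.null(data$y_true)) df$y_true <- data$y_true
  if (!is.null(data$subclass)) df$subclass <- data$subclass
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
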