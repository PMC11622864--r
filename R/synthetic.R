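# Seeded SCAR / SNAR synthetic PU data generators.  Classes (negative plus
# one or more positive subclasses) live in an informative-feature subspace:
# each class is standard Gaussian pushed through its own random linear
# transform (entries uniform on [-1, 1], so classes differ in covariance)
# and shifted to a distinct hypercube vertex scaled by `class_sep`; the
# remaining features are pure noise.  Small `class_sep` (default 0.3) means
# the class means barely differ and separation rests on the covariance
# structure — a genuinely hard classification problem.

#' Specification of a synthetic PU dataset
#'
#' Collects the knobs of the SCAR/SNAR generators.  Defaults mirror the
#' simulation recipes used throughout the package's tests: 2,000 labeled
#' positives, 6,000 unlabeled examples, 50 features of which 10 are
#' informative, `class_sep = 0.3`.  For SNAR data with five subclasses the
#' default hidden-positive proportions are 1/31, 2/31, 4/31, 8/31, 16/31 —
#' a strongly skewed subtype mix, while the labeled positives are balanced
#' across subclasses, which is exactly the labeling bias SNAR describes.
#'
#' @param n_pos number of labeled positives.
#' @param n_unl number of unlabeled examples.
#' @param frac_k percent (0-100, exclusive of 100) of the unlabeled set
#'   that are hidden positives; true `alpha = frac_k / 100`.
#' @param n_features total number of features.
#' @param n_informative number of informative features (the rest are
#'   noise); must satisfy `2^n_informative >= n_subclasses + 1`.
#' @param class_sep half-side of the centroid hypercube; larger separates
#'   the classes more.
#' @param n_subclasses number of positive subclasses (1 = SCAR).
#' @param subclass_props proportions of the hidden unlabeled positives in
#'   each subclass; defaults to the doubling sequence
#'   `2^(0:(n-1)) / (2^n - 1)` (for 5 subclasses: 1/31 ... 16/31).
#' @param seed integer seed.
#' @return An object of class `pu_synth_spec`.
#' @export
pu_synth_spec <- function(n_pos = 2000, n_unl = 6000, frac_k = 10,
                          n_features = 50, n_informative = min(10, n_features),
                          class_sep = 0.3, n_subclasses = 1,
                          subclass_props = NULL, seed = 0) {
  stopifnot(n_pos >= 1, n_unl >= 1, n_features >= 1,
            n_informative >= 1, n_informative <= n_features,
            class_sep > 0, n_subclasses >= 1)
  if (frac_k < 0 || frac_k >= 100) {
    stop("'frac_k' must lie in [0, 100)", call. = FALSE)
  }
  if (is.null(subclass_props)) {
    subclass_props <- 2^(seq_len(n_subclasses) - 1) /
      (2^n_subclasses - 1)
  }
  stopifnot(length(subclass_props) == n_subclasses,
            isTRUE(all.equal(sum(subclass_props), 1)),
            all(subclass_props >= 0))
  if (2^n_informative < n_subclasses + 1) {
    stop("need 2^n_informative >= n_subclasses + 1 distinct centroids",
         call. = FALSE)
  }
  structure(list(n_pos = as.integer(n_pos), n_unl = as.integer(n_unl),
                 frac_k = frac_k, n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_sep = class_sep,
                 n_subclasses = as.integer(n_subclasses),
                 subclass_props = subclass_props, seed = as.integer(seed)),
            class = "pu_synth_spec")
}

# Distinct hypercube-vertex centroids (one per class: negative first,
# then the positive subclasses), scaled by class_sep.  Vertices are drawn
# by rejection so arbitrary n_informative works without enumerating 2^d.
class_centroids <- function(n_classes, n_informative, class_sep) {
  seen <- character(0)
  signs <- matrix(0, n_classes, n_informative)
  i <- 1
  while (i <= n_classes) {
    v <- sample(c(-1, 1), n_informative, replace = TRUE)
    key <- paste(v, collapse = "")
    if (!key %in% seen) {
      seen <- c(seen, key)
      signs[i, ] <- v
      i <- i + 1
    }
  }
  signs * class_sep
}

# Draw n points of one class: informative block = standard normal times
# the class's random transform, plus the centroid; remaining features are
# standard normal noise.
draw_class <- function(n, centroid, transform, n_features) {
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  ni <- length(centroid)
  x[, seq_len(ni)] <- x[, seq_len(ni), drop = FALSE] %*% transform +
    matrix(centroid, n, ni, byrow = TRUE)
  x
}

# One random linear map per class (entries uniform on [-1, 1]); gives each
# class its own covariance, which carries most of the class signal when
# class_sep is small.
class_transforms <- function(n_classes, n_informative) {
  lapply(seq_len(n_classes), function(i) {
    matrix(stats::runif(n_informative^2, -1, 1), n_informative, n_informative)
  })
}

# Shared generator: counts per class for labeled positives, hidden
# positives (by subclass) and negatives; returns a pu_dataset.
generate_pu <- function(spec, labeled_per_subclass, hidden_per_subclass) {
  n_hidden <- sum(hidden_per_subclass)
  n_neg <- spec$n_unl - n_hidden
  stopifnot(n_neg >= 0)
  withr::with_seed(spec$seed, {
    centroids <- class_centroids(spec$n_subclasses + 1,
                                 spec$n_informative, spec$class_sep)
    transforms <- class_transforms(spec$n_subclasses + 1,
                                   spec$n_informative)
    blocks <- list()
    s <- integer(0); y <- integer(0); sub <- integer(0)
    # labeled positives, balanced across subclasses
    for (j in seq_len(spec$n_subclasses)) {
      nj <- labeled_per_subclass[j]
      if (nj > 0) {
        blocks[[length(blocks) + 1]] <-
          draw_class(nj, centroids[j + 1, ], transforms[[j + 1]],
                     spec$n_features)
        s <- c(s, rep(1L, nj)); y <- c(y, rep(1L, nj))
        sub <- c(sub, rep(j, nj))
      }
    }
    # hidden positives in the unlabeled set
    for (j in seq_len(spec$n_subclasses)) {
      nj <- hidden_per_subclass[j]
      if (nj > 0) {
        blocks[[length(blocks) + 1]] <-
          draw_class(nj, centroids[j + 1, ], transforms[[j + 1]],
                     spec$n_features)
        s <- c(s, rep(0L, nj)); y <- c(y, rep(1L, nj))
        sub <- c(sub, rep(j, nj))
      }
    }
    # negatives
    if (n_neg > 0) {
      blocks[[length(blocks) + 1]] <-
        draw_class(n_neg, centroids[1, ], transforms[[1]], spec$n_features)
      s <- c(s, rep(0L, n_neg)); y <- c(y, rep(0L, n_neg))
      sub <- c(sub, rep(0L, n_neg))
    }
    x <- do.call(rbind, blocks)
    # shuffle the unlabeled block so hidden positives are interleaved
    unl <- which(s == 0L)
    perm <- sample(unl)
    x[unl, ] <- x[perm, ]
    y[unl] <- y[perm]
    sub[unl] <- sub[perm]
    pu_dataset(x, s, y_true = y, subclass = sub)
  })
}

#' Generate a SCAR synthetic PU dataset
#'
#' One positive class: the unlabeled set contains
#' `round(frac_k/100 * n_unl)` hidden positives drawn from the same
#' distribution as the labeled positives (labeling completely at random)
#' plus negatives.
#'
#' @param spec a [pu_synth_spec()] with `n_subclasses = 1`.
#' @return A [pu_dataset()] with `y_true` and `subclass` recorded.
#' @examples
#' d <- make_scar(pu_synth_spec(n_pos = 50, n_unl = 100, frac_k = 10,
#'                              n_features = 5, n_informative = 3, seed = 1))
#' sum(d$y_true == 1 & d$s == 0)  # 10 hidden positives
#' @export
make_scar <- function(spec) {
  stopifnot(inherits(spec, "pu_synth_spec"))
  if (spec$n_subclasses != 1) {
    stop("make_scar requires n_subclasses = 1 (use make_snar)", call. = FALSE)
  }
  n_hidden <- round(spec$frac_k / 100 * spec$n_unl)
  generate_pu(spec, labeled_per_subclass = spec$n_pos,
              hidden_per_subclass = n_hidden)
}

#' Generate a SNAR synthetic PU dataset
#'
#' Positive subclasses are their own Gaussian clusters.  Labeled positives
#' are split equally across subclasses while the hidden unlabeled
#' positives follow `subclass_props` (largest-remainder integerization),
#' so a positive's chance of being labeled depends on its subtype — the
#' SNAR violation.  With the default five-subclass proportions and
#' `n_unl = 6000`, `frac_k = 20`, the per-subclass hidden counts are
#' 39, 77, 155, 310, 619 with 4,800 negatives.
#'
#' @param spec a [pu_synth_spec()] with `n_subclasses >= 2`.
#' @return A [pu_dataset()] with `y_true` and `subclass` recorded.
#' @export
make_snar <- function(spec) {
  stopifnot(inherits(spec, "pu_synth_spec"))
  if (spec$n_subclasses < 2) {
    stop("make_snar requires n_subclasses >= 2 (use make_scar)", call. = FALSE)
  }
  n_hidden <- round(spec$frac_k / 100 * spec$n_unl)
  hidden <- if (n_hidden > 0) {
    largest_remainder(spec$subclass_props, n_hidden)
  } else rep(0L, spec$n_subclasses)
  if (any(hidden == 0) && n_hidden > 0) {
    message("some subclasses received 0 hidden positives at this frac_k")
  }
  labeled <- largest_remainder(rep(1, spec$n_subclasses), spec$n_pos)
  generate_pu(spec, labeled_per_subclass = labeled,
              hidden_per_subclass = hidden)
}

#' Positive-injection plan for benchmark-style PU construction
#'
#' To make an unlabeled set contain `k` percent hidden positives by
#' flipping labeled positives to unlabeled, the number of records to flip
#' is `m = round(k * |U| / (100 - k))`, after which the enlarged unlabeled
#' set of size `|U| + m` contains `m` hidden positives — a `k`% fraction
#' (up to rounding).
#'
#' @param n_pos_available labeled positives available for flipping.
#' @param n_unl current size of the unlabeled set.
#' @param k target hidden-positive percentage of the enlarged unlabeled
#'   set, in \[0, 100).
#' @param seed integer seed for the random selection.
#' @return List with `m` (number to flip) and `flip_idx` (indices into
#'   the positive set, seeded random sample).
#' @examples
#' inject_flipped_positives(500, 900, 10, seed = 1)$m  # 100
#' @export
inject_flipped_positives <- function(n_pos_available, n_unl, k, seed = 1) {
  stopifnot(n_pos_available >= 0, n_unl >= 0)
  if (k < 0 || k >= 100) stop("'k' must lie in [0, 100)", call. = FALSE)
  m <- round(k * n_unl / (100 - k))
  if (m > n_pos_available) {
    stop(sprintf("need %d positives to flip but only %d are available",
                 m, n_pos_available), call. = FALSE)
  }
  flip_idx <- if (m > 0) {
    withr::with_seed(seed, sample(n_pos_available, m))
  } else integer(0)
  list(m = as.integer(m), flip_idx = flip_idx)
}
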