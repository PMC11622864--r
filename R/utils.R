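# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Every stochastic step in the package receives its own seed derived
#' deterministically from the caller's master seed, so that a single integer
#' reproduces a whole pipeline run.  Kept below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param offset integer offset identifying the consumer.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %% 2147483647)
}

# Largest-remainder (Hamilton) apportionment of `total` into integer parts
# proportional to `weights`.  Exact: parts always sum to `total`.
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- total * weights / sum(weights)
  parts <- floor(quota)
  short <- as.integer(round(total - sum(parts)))
  if (short > 0) {
    extra <- order(quota - parts, decreasing = TRUE)[seq_len(short)]
    parts[extra] <- parts[extra] + 1
  }
  as.integer(parts)
}

check_prob_vector <- function(x, name = deparse(substitute(x)), allow_empty = FALSE) {
  if (!allow_empty && length(x) == 0) {
    stop(sprintf("'%s' must contain at least one value", name), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  if (length(x) && (min(x) < 0 || max(x) > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(alpha)
}

# Assign values in [0,1] to 1-based equal-width bins over [0,1]
# (right-open bins, last bin right-closed).
prob_bin_index <- function(x, n_bins) {
  pmin(floor(x * n_bins) + 1L, as.integer(n_bins))
}
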