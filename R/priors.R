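#' Label frequency and class prior implied by an alpha estimate
#'
#' Under SCAR the label frequency `p(s=1 | y=1)` is a constant linking the
#' observable labeled fraction to the (unidentifiable) class prior.  Given
#' the counts of labeled positives and unlabeled examples and an estimate
#' of `alpha` (the fraction of unlabeled examples that are truly
#' positive), the three quantities are:
#'
#' \deqn{p(s=1) = |P| / (|P|+|U|)}
#' \deqn{p(y=1) = (|P| + \alpha|U|) / (|P|+|U|)}
#' \deqn{p(s=1|y=1) = |P| / (|P| + \alpha|U|)}
#'
#' so that `label_frequency * p_y1 = p_s1` exactly.
#'
#' @param n_pos number of labeled positives, `|P|`.
#' @param n_unl number of unlabeled examples, `|U|`.
#' @param alpha fraction of unlabeled examples that are positive, in \[0,1\].
#' @return An object of class `prior_summary`: list with `p_s1`, `p_y1`,
#'   `label_frequency`.
#' @examples
#' label_frequency_and_prior(2000, 6000, 0.1)
#' @export
label_frequency_and_prior <- function(n_pos, n_unl, alpha) {
  stopifnot(n_pos >= 0, n_unl >= 0, n_pos + n_unl > 0)
  check_alpha(alpha)
  p_s1 <- n_pos / (n_pos + n_unl)
  p_y1 <- (n_pos + alpha * n_unl) / (n_pos + n_unl)
  lf <- if (n_pos + alpha * n_unl > 0) n_pos / (n_pos + alpha * n_unl) else NA_real_
  structure(list(p_s1 = p_s1, p_y1 = p_y1, label_frequency = lf),
            class = "prior_summary")
}

#' @export
print.prior_summary <- function(x, ...) {
  cat(sprintf("p(s=1) = %.4f | p(y=1) = %.4f | label frequency p(s=1|y=1) = %.4f\n",
              x$p_s1, x$p_y1, x$label_frequency))
  invisible(x)
}
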