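test_that("flip counts are exactly conserved", {
  withr::with_seed(1, {
    pos <- rbeta(300, 4, 2)
    unl <- rbeta(50, 2, 4)
  })
  # alpha = 0: nothing flips
  fl0 <- flip_by_positive_histogram(pos, unl, 0, n_bins = 10, seed = 1)
  expect_identical(sum(fl0$flipped), 0L)
  # |U| = 50, alpha = 0.1: exactly 5 flips
  fl <- flip_by_positive_histogram(pos, unl, 0.1, n_bins = 10, seed = 1)
  expect_identical(sum(fl$flipped), 5L)
  expect_identical(sum(fl$per_bin_flip_counts), 5L)
})

test_that("over-demanded bins carry their shortfall to the next lower bin", {
  # positives all in the top bin -> top bin demands all 5 flips, but only
  # 2 unlabeled examples live there; 3 must carry downward
  pos <- rep(0.99, 100)
  unl <- c(rep(0.95, 2), rep(0.85, 10), rep(0.2, 38))
  fl <- flip_by_positive_histogram(pos, unl, 0.1, n_bins = 10, seed = 3)
  expect_identical(sum(fl$flipped), 5L)
  expect_identical(fl$per_bin_flip_counts[10], 2L)  # bin (0.9, 1]
  expect_identical(fl$per_bin_flip_counts[9], 3L)   # carried down
  expect_true(all(fl$flipped[unl == 0.95] == 1))
})

test_that("flipped examples mirror the positive histogram shape", {
  withr::with_seed(2, {
    pos <- rbeta(5000, 6, 2)
    unl <- runif(2000)
  })
  fl <- flip_by_positive_histogram(pos, unl, 0.3, n_bins = 10, seed = 1)
  expect_identical(sum(fl$flipped), 600L)
  pos_mass <- tabulate(pmin(floor(pos * 10) + 1, 10), 10) / 5000
  # per-bin counts within a few of the ideal apportionment
  expect_lt(max(abs(fl$per_bin_flip_counts - 600 * pos_mass)), 25)
})

test_that("flip conservation holds across random (alpha, |U|) configurations", {
  withr::with_seed(4, {
    for (i in 1:30) {
      nu <- sample(20:500, 1)
      a <- runif(1)
      pos <- rbeta(sample(50:500, 1), runif(1, 0.5, 6), runif(1, 0.5, 6))
      unl <- rbeta(nu, runif(1, 0.5, 6), runif(1, 0.5, 6))
      fl <- flip_by_positive_histogram(pos, unl, a, n_bins = 100, seed = i)
      expect_identical(sum(fl$flipped), as.integer(round(a * nu)))
      expect_identical(sum(fl$per_bin_flip_counts), as.integer(round(a * nu)))
    }
  })
})

test_that("isotonic calibration preserves the label mean and monotonicity", {
  withr::with_seed(5, {
    p <- runif(400)
    y <- rbinom(400, 1, p^2)
  })
  cal <- fit_calibrator(p, y, "isotonic")
  expect_equal(mean(cal), mean(y), tolerance = 1e-9)
  ord <- order(p)
  expect_true(all(diff(cal[ord]) >= -1e-12))
  # separable labels give a 0/1 step
  ps <- seq(0.05, 0.95, length.out = 20)
  ys <- as.integer(ps > 0.5)
  cs <- fit_calibrator(ps, ys, "isotonic")
  expect_equal(sort(unique(round(cs, 9))), c(0, 1))
})

test_that("sigmoid calibration is strictly monotone in the score", {
  withr::with_seed(6, {
    p <- runif(300)
    y <- rbinom(300, 1, p)
  })
  cal <- fit_calibrator(p, y, "sigmoid")
  ord <- order(p)
  expect_true(all(diff(cal[ord]) > 0 | diff(p[ord]) == 0))
})

test_that("single-class labels yield the constant class rate with a warning", {
  expect_warning(cal <- fit_calibrator(runif(10), rep(1, 10), "isotonic"),
                 "single-class")
  expect_equal(as.numeric(cal), rep(1, 10))
})

test_that("cluster probability combination follows the no-subclass complement", {
  expect_equal(combine_cluster_probabilities(c(0, 0, 0)), 0)
  expect_equal(combine_cluster_probabilities(c(0.3, 1, 0.2)), 1)
  expect_equal(combine_cluster_probabilities(c(0.5, 0.5)), 0.75)
  expect_error(combine_cluster_probabilities(numeric(0)), "empty")
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- runif(sample(1:6, 1))
      v <- combine_cluster_probabilities(p)
      expect_equal(v, combine_cluster_probabilities(rev(p)), tolerance = 1e-12)
      expect_gte(v + 1e-12, max(p))
      expect_lte(v, 1)
    }
  })
})

make_scored_toy <- function(n_pos = 400, n_unl = 1000, alpha = 0.2, seed = 8) {
  withr::with_seed(seed, {
    p_pos <- rbeta(n_pos, 5, 2)
    n_hid <- round(alpha * n_unl)
    p_unl <- c(rbeta(n_hid, 5, 2), rbeta(n_unl - n_hid, 2, 5))
  })
  d <- pu_dataset(matrix(0, n_pos + n_unl, 1),
                  s = c(rep(1L, n_pos), rep(0L, n_unl)))
  list(d = d, scored = list(p = c(p_pos, p_unl)))
}

test_that("scope-U isotonic calibrated probabilities sum to alpha|U|", {
  toy <- make_scored_toy(alpha = 0.2)
  cal <- calibrate_pu(toy$d, toy$scored, alpha = 0.2, scope = "U", seed = 1)
  expect_lt(abs(sum(cal$calibrated, na.rm = TRUE) - round(0.2 * 1000)), 0.5)
  expect_true(all(is.na(cal$calibrated[toy$d$s == 1])))
  expect_identical(cal$n_flipped, 200L)
})

test_that("scope-PU isotonic calibrated probabilities sum to |P| + alpha|U|", {
  toy <- make_scored_toy(n_pos = 500, n_unl = 2000, alpha = 0.3, seed = 9)
  cal <- calibrate_pu(toy$d, toy$scored, alpha = 0.3, scope = "PU", seed = 2)
  expect_lt(abs(sum(cal$calibrated) - (500 + 0.3 * 2000)), 1)
  # flips only among unlabeled rows; positives keep label 1
  expect_true(all(cal$flipped_labels[toy$d$s == 1] == 1))
})

test_that("alpha = 0 with scope U calibrates everything to zero", {
  toy <- make_scored_toy(alpha = 0)
  expect_warning(
    cal <- calibrate_pu(toy$d, toy$scored, alpha = 0, scope = "U", seed = 1),
    "single-class"
  )
  expect_equal(max(cal$calibrated[toy$d$s == 0]), 0)
})
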