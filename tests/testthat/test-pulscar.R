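grid2 <- function(D) {
  structure(list(z = seq(0, 1, length.out = length(D)), D = D,
                 bw = 0.1, n_bins = length(D)),
            class = "density_grid")
}

test_that("mixture-gap objective matches hand evaluation", {
  Du <- grid2(c(1, 1))
  Dp <- grid2(c(2, 0.5))
  # alpha = 0.2: min diff = min(1 - 0.4, 1 - 0.1) = 0.6, eps = 0.5
  expect_equal(pu_objective(0.2, Du, Dp), log(1.1), tolerance = 1e-12)
  # alpha = 0: min diff 1, eps 0.5
  expect_equal(pu_objective(0, Du, Dp), log(1.5), tolerance = 1e-12)
  # identical grids with a zero bin force the 1e-10 floor at alpha = 1
  D0 <- grid2(c(0, 2))
  expect_equal(pu_objective(1, D0, D0), log(1e-10), tolerance = 1e-9)
  # vectorized over alpha
  expect_equal(pu_objective(c(0, 0.2), Du, Dp), c(log(1.5), log(1.1)))
  expect_error(pu_objective(0.5, Du, grid2(c(1, 1, 1))), "identical grids")
})

test_that("alpha_max is the clipped minimum density ratio over valid bins", {
  expect_equal(alpha_max(grid2(c(0.5, 1.5)), grid2(c(1, 1))), 0.5)
  D <- grid2(c(0.3, 1, 2))
  expect_equal(alpha_max(D, D), 1.0)
  # zero-Dp bins are ignored
  expect_equal(alpha_max(grid2(c(1, 1)), grid2(c(0, 2))), 0.5)
  expect_error(alpha_max(grid2(c(1, 1)), grid2(c(0, 0))), "zero")
})

test_that("slope-change alpha equals the min-ratio oracle on constructed mixtures", {
  # D_u = alpha*D_p + (1-alpha)*D_n with D_n supported away from D_p's
  # mode: the first sharp change must sit at alpha_max = alpha
  for (alpha in c(0.05, 0.2, 0.45, 0.8)) {
    pair <- constructed_density_pair(alpha)
    fit <- pulscar_from_densities(pair$Du, pair$Dp)
    expect_equal(fit$alpha_max, alpha, tolerance = 1e-9)
    expect_lt(abs(fit$alpha_hat - alpha), 2 * 1e-4 + 1e-12)
  }
})

test_that("estimated alpha always lies on the 1e-4 grid inside (0, 1]", {
  withr::with_seed(13, {
    for (i in 1:4) {
      fit <- pulscar(rbeta(400, 3, 2), rbeta(400, 2, 3), n_bins = 25, seed = i)
      expect_gte(fit$alpha_hat, 1e-4)
      expect_lte(fit$alpha_hat, 1)
      expect_equal(fit$alpha_hat * 1e4, round(fit$alpha_hat * 1e4),
                   tolerance = 1e-9)
    }
  })
})

test_that("identical probability distributions give alpha near 1", {
  withr::with_seed(17, {
    pos <- rbeta(5000, 3, 3)
    unl <- rbeta(5000, 3, 3)
  })
  fit <- pulscar(pos, unl, seed = 1)
  expect_gte(fit$alpha_hat, 0.9)
})

test_that("well-separated probability distributions give alpha near 0", {
  withr::with_seed(19, {
    pos <- rbeta(5000, 8, 2)
    unl <- rbeta(5000, 2, 8)
  })
  fit <- pulscar(pos, unl, seed = 1)
  expect_lte(fit$alpha_hat, 0.05)
})

test_that("implied negative density stays above -epsilon everywhere", {
  withr::with_seed(23, {
    pos <- rbeta(2000, 6, 3)
    unl <- c(rbeta(600, 6, 3), rbeta(1400, 2, 6))  # 30% positives
  })
  fit <- pulscar(pos, unl, seed = 2)
  Dp <- beta_kernel_density(pos, fit$curve$bw, fit$curve$n_bins)
  Du <- beta_kernel_density(unl, fit$curve$bw, fit$curve$n_bins)
  # admissibility up to the alpha-grid resolution: one 1e-4 step of alpha
  # can change the gap by at most 1e-4 * max(Dp)
  slack <- fit$curve$epsilon + 1e-4 * max(Dp$D)
  expect_true(all(Du$D - fit$alpha_hat * Dp$D >= -slack))
  expect_lte(fit$alpha_hat, fit$alpha_max + 1e-4 + 1e-12)
})

test_that("first_sharp_change picks the earliest prominent peak", {
  # two-bump mixture where the admissible change point comes before the
  # global minimum of the objective
  pair <- constructed_density_pair(0.25)
  f1 <- pulscar_from_densities(pair$Du, pair$Dp, mode = "first_sharp_change")
  f2 <- pulscar_from_densities(pair$Du, pair$Dp, mode = "max_slope_change")
  expect_lte(f1$alpha_hat, f2$alpha_hat + 1e-12)
  expect_lt(abs(f1$alpha_hat - 0.25), 2e-4 + 1e-12)
})

test_that("degenerate single-bin probabilities raise a diagnostic error", {
  expect_error(pulscar(rep(0.501, 50), rep(0.502, 50), n_bins = 10, seed = 1),
               "degenerate")
})

test_that("pulscar is deterministic given data and seed", {
  withr::with_seed(29, {
    pos <- rbeta(500, 4, 2)
    unl <- rbeta(500, 2, 4)
  })
  f1 <- pulscar(pos, unl, n_bins = 30, seed = 11)
  f2 <- pulscar(pos, unl, n_bins = 30, seed = 11)
  expect_identical(f1$alpha_hat, f2$alpha_hat)
  expect_identical(f1$curve$bw, f2$curve$bw)
})

test_that("mean alpha estimate is non-decreasing in the true mixture fraction", {
  # direct mixture of known score distributions, several seeds
  mean_hat <- vapply(c(0.1, 0.3, 0.5), function(a) {
    hats <- vapply(1:3, function(sd) {
      withr::with_seed(100 * sd, {
        pos <- rbeta(1500, 5, 2)
        unl <- c(rbeta(round(a * 1500), 5, 2),
                 rbeta(1500 - round(a * 1500), 2, 5))
      })
      pulscar(pos, unl, n_bins = 40, seed = sd)$alpha_hat
    }, numeric(1))
    mean(hats)
  }, numeric(1))
  expect_true(all(diff(mean_hat) >= 0))
})
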