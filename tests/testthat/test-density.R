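test_that("beta kernel density matches hand-evaluated Beta densities", {
  # single point x = 0.3, bw = 0.5: at z = 0, (a, b) = (1, 3); at z = 1, (3, 1)
  g <- beta_kernel_density(0.3, bw = 0.5, n_bins = 3)
  expect_equal(g$D[1], 3 * (1 - 0.3)^2, tolerance = 1e-12)  # 1.47
  expect_equal(g$D[3], 3 * 0.3^2, tolerance = 1e-12)        # 0.27
  # mid-grid value against stats::dbeta on the same (a, b)
  expect_equal(g$D[2], dbeta(0.3, 2, 2), tolerance = 1e-12)
  expect_identical(g$z, c(0, 0.5, 1))
})

test_that("beta kernel agrees with dbeta averaging for a random sample", {
  withr::with_seed(11, x <- rbeta(200, 2, 5))
  g <- beta_kernel_density(x, bw = 0.2, n_bins = 17)
  j <- c(1, 5, 9, 17)
  a <- 1 + g$z / 0.2
  b <- 1 + (1 - g$z) / 0.2
  for (jj in j) {
    expect_equal(g$D[jj], mean(dbeta(x, a[jj], b[jj])), tolerance = 1e-10)
  }
})

test_that("kernel symmetry: data at 0.5 gives a symmetric density", {
  g <- beta_kernel_density(0.5, bw = 0.3, n_bins = 21)
  expect_equal(g$D, rev(g$D), tolerance = 1e-12)
})

test_that("boundary data values 0 and 1 produce finite nonnegative density", {
  g <- beta_kernel_density(c(0, 1, 0.5), bw = 0.1, n_bins = 11)
  expect_true(all(is.finite(g$D)))
  expect_true(all(g$D >= 0))
  # at z = 0 the kernel for x = 0 is the Beta(1, 1 + 1/bw) density at 0
  expect_equal(g$D[1], mean(dbeta(c(0, 1, 0.5), 1, 1 + 1 / 0.1)),
               tolerance = 1e-10)
})

test_that("beta kernel validates its inputs", {
  expect_error(beta_kernel_density(numeric(0), 0.1, 10), "at least one")
  expect_error(beta_kernel_density(0.5, 0.005, 10), "bw")
  expect_error(beta_kernel_density(0.5, 0.7, 10), "bw")
  expect_error(beta_kernel_density(1.5, 0.1, 10), "0, 1")
})

test_that("density nonnegativity and approximate mass conservation hold", {
  withr::with_seed(3, {
    samples <- list(runif(400), rbeta(400, 8, 2), rbeta(400, 2, 5))
  })
  # mass conservation is approximate: it degrades for very wide kernels on
  # strongly skewed samples (boundary kernels lose mass), so it is asserted
  # over the bandwidth regime the estimators actually select
  for (x in samples) {
    for (bw in c(0.01, 0.05, 0.1, 0.2)) {
      g <- beta_kernel_density(x, bw, n_bins = 50)
      expect_true(all(g$D >= 0))
      mass <- sum(diff(g$z) * (head(g$D, -1) + tail(g$D, -1)) / 2)
      expect_lt(abs(mass - 1), 0.05)
    }
  }
  # positivity alone must hold over the whole bandwidth range
  for (x in samples) {
    expect_true(all(beta_kernel_density(x, 0.5, n_bins = 50)$D >= 0))
  }
})

test_that("bin-count rules reproduce their printed formulae", {
  expect_identical(histogram_bin_count(runif(10000), "sqrt"), 100L)
  expect_identical(histogram_bin_count(runif(1024), "sturges"), 11L)
  expect_identical(histogram_bin_count(runif(1000), "rice"), 20L)
  expect_identical(histogram_bin_count(c(0.1, 0.9), "sqrt"), 2L)  # floor at 2
})

test_that("FD rule hand example: width 0.04 over range 0.8 gives 20 bins", {
  # sample engineered to have IQR exactly 0.2 and range exactly 0.8:
  # n = 1000 so n^(1/3) = 10, width h = 2 * 0.2 / 10 = 0.04, 0.8 / h = 20
  x <- c(0.1, rep(0.3, 499), rep(0.5, 499), 0.9)
  expect_equal(unname(diff(quantile(x, c(0.25, 0.75)))), 0.2)
  expect_identical(histogram_bin_count(x, "fd"), 20L)
})

test_that("scott/fd fall back to sqrt on zero spread, with a warning", {
  x <- rep(0.4, 100)
  expect_warning(nb <- histogram_bin_count(x, "scott"), "sqrt")
  expect_identical(nb, 10L)
  expect_warning(nb2 <- histogram_bin_count(x, "fd"), "sqrt")
  expect_identical(nb2, 10L)
})

test_that("histogram density is normalized and maps mass to bins", {
  # uniform grid: every bin density 1
  g <- histogram_density(seq(0.005, 0.995, length.out = 100), 10)
  expect_equal(g$bin_density, rep(1, 10), tolerance = 1e-12)
  # all mass in one bin: density n_bins there, 0 elsewhere
  g1 <- histogram_density(rep(0.55, 7), 10)
  expect_equal(g1$bin_density[6], 10)
  expect_equal(sum(g1$bin_density != 0), 1)
  # normalization contract
  withr::with_seed(8, x <- rbeta(333, 3, 1))
  g2 <- histogram_density(x, 13)
  expect_equal(sum(g2$bin_density) / 13, 1, tolerance = 1e-9)
  expect_error(histogram_density(x, 1), ">= 2")
})

test_that("bandwidth search matches an exhaustive grid oracle", {
  withr::with_seed(21, x <- rbeta(2000, 4, 4))  # symmetric unimodal
  n_bins <- histogram_bin_count(x, "sqrt")
  bw <- estimate_bandwidth(x, n_bins, seed = 5)
  expect_gte(bw, 0.01)
  expect_lte(bw, 0.5)
  oracle <- oracle_grid_bandwidth(x, n_bins)
  expect_lt(abs(bw - oracle$bw), 0.02)
})

test_that("bandwidth at the optimum beats both interval endpoints", {
  withr::with_seed(31, x <- rbeta(1200, 2, 6))
  n_bins <- 35
  z <- seq(0, 1, length.out = n_bins)
  dh <- histogram_density(x, n_bins)$D
  mse <- function(bw) mean((dh - beta_kernel_density(x, bw, n_bins)$D)^2)
  bw <- estimate_bandwidth(x, n_bins, seed = 2)
  expect_lte(mse(bw), mse(0.01))
  expect_lte(mse(bw), mse(0.5))
})

test_that("bandwidth search is seed-reproducible and total on degenerate input", {
  withr::with_seed(4, x <- rbeta(300, 5, 3))
  expect_identical(estimate_bandwidth(x, 20, seed = 7),
                   estimate_bandwidth(x, 20, seed = 7))
  bw <- estimate_bandwidth(rep(0.5, 50), 10, seed = 1)
  expect_gte(bw, 0.01)
  expect_lte(bw, 0.5)
})
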