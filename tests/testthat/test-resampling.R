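# Permutation and bootstrap inference for the peak-to-peak statistic.

test_that("permutation test is reproducible and p-values have 1/n_perm resolution", {
  d <- make_xy(300, a = 1, w = 2.24, noise_sd = 8, seed = 1)
  r1 <- permutation_test_serial_bias(d$x, d$y, n_perm = 100, n_boot = 50, seed = 42)
  r2 <- permutation_test_serial_bias(d$x, d$y, n_perm = 100, n_boot = 50, seed = 42)
  expect_identical(r1$null_p2p, r2$null_p2p)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  # plain proportion of 100 permutations: must be a multiple of 0.01
  expect_equal(r1$p_value * 100, round(r1$p_value * 100))
  expect_length(r1$null_p2p, 100)
  expect_error(permutation_test_serial_bias(d$x, d$y, n_perm = 0),
               class = "sb_invalid_argument")
})

test_that("an observed statistic of exactly zero yields p = 1", {
  x <- seq(-pi / 2, pi / 2, length.out = 50)
  y <- rep(0, 50) # fit is a = 0, p2p = 0; every null value is >= in magnitude
  r <- permutation_test_serial_bias(x, y, n_perm = 25, seed = 5)
  expect_equal(r$p2p, 0)
  expect_equal(r$p_value, 1)
})

test_that("a strong injected bias is detected at large n", {
  d <- make_xy(5000, a = 2, w = 2.24, noise_sd = 8, seed = 2)
  r <- permutation_test_serial_bias(d$x, d$y, n_perm = 200, seed = 9)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$p2p, 0)
})

test_that("the null p2p distribution is sign-symmetric under exchangeable noise", {
  d <- make_xy(800, a = 0, noise_sd = 10, seed = 3)
  r <- permutation_test_serial_bias(d$x, d$y, n_perm = 400, seed = 10)
  expect_lt(abs(median(r$null_p2p)), 1)   # centred near zero
  expect_gt(mean(r$null_p2p > 0), 0.35)   # neither sign dominates
  expect_lt(mean(r$null_p2p > 0), 0.65)
})

test_that("bootstrap CI brackets the true effect and orders its endpoints", {
  d <- make_xy(3000, a = 1.25, w = 2.24, noise_sd = 8, seed = 6)
  ci <- bootstrap_p2p_ci(d$x, d$y, n_boot = 300, seed = 12)
  expect_lte(ci$ci_low, ci$ci_high)
  expect_gt(ci$ci_high, 0) # attractive bias: upper end above zero
  expect_true(ci$ci_low <= quantile(ci$boot_p2p, 0.5))
  expect_error(bootstrap_p2p_ci(d$x, d$y, n_boot = 50, level = 1.2),
               class = "sb_invalid_argument")
})

test_that("condition-difference test: identical groups give zero difference and p = 1", {
  d <- make_xy(300, a = 1, w = 2, noise_sd = 6, seed = 13)
  r <- permutation_test_condition_difference(d$x, d$y, d$x, d$y,
                                             n_perm = 50, seed = 14)
  expect_equal(r$difference, 0)
  expect_equal(r$p_value, 1)
})

test_that("condition-difference test detects opposite-sign biases", {
  a_grp <- make_xy(2500, a = 1.25, w = 2.24, noise_sd = 8, seed = 15)
  b_grp <- make_xy(2500, a = -1.25, w = 2.24, noise_sd = 8, seed = 16)
  r <- permutation_test_condition_difference(a_grp$x, a_grp$y, b_grp$x, b_grp$y,
                                             n_perm = 200, seed = 17)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$difference, 5, tolerance = 1.5) # 2a - (-2a) = 5 deg
  expect_error(
    permutation_test_condition_difference(a_grp$x[1:2], a_grp$y[1:2],
                                          b_grp$x, b_grp$y, n_perm = 10),
    class = "sb_insufficient_data")
})
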