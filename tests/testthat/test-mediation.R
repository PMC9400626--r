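# AICc arithmetic and direct / indirect / null model comparison.

test_that("aicc matches the closed-form correction", {
  expect_equal(aicc(sse = 10, n = 10, k = 2), 4 + 12 / 7)
  expect_equal(aicc(sse = 7, n = 20, k = 0), 20 * log(7 / 20))
  expect_error(aicc(sse = 10, n = 3, k = 2), class = "sb_invalid_argument")
  expect_error(aicc(sse = -1, n = 10, k = 2), class = "sb_invalid_argument")
  # monotone increasing in sse for fixed n, k
  sses <- c(0.5, 1, 2, 5, 50)
  vals <- vapply(sses, aicc, numeric(1), n = 30, k = 2)
  expect_true(all(diff(vals) > 0))
  # optional convention counting the noise variance
  expect_equal(aicc(10, 20, 2, count_sigma = TRUE), aicc(10, 20, 3))
})

test_that("fit_indirect with a vanishing stage 1 matches the direct fit on item C", {
  withr::with_seed(40, {
    n <- 600
    ori_C <- sample(0:179, n, TRUE)
    ori_imi <- sample(0:179, n, TRUE)
    sample1 <- sample(0:179, n, TRUE)
    x_C <- wrap_angle_180(ori_C - sample1) * pi / 180
    y <- dog_predict(x_C, list(a = 0.8, w = 3))
    ind <- fit_indirect(wrap_angle_180(ori_imi - ori_C) * pi / 180,
                        ori_C, sample1, y)
    dir <- fit_dog(x_C, y)
    expect_equal(ind$a2, dir$a, tolerance = 1e-4)
    expect_equal(ind$w2, dir$w, tolerance = 1e-4)
    expect_lt(abs(ind$a1), 1e-3)
  })
})

test_that("fit_indirect recovers all four parameters from noiseless data", {
  withr::with_seed(41, {
    n <- 800
    ori_C <- sample(0:179, n, TRUE)
    ori_imi <- sample(0:179, n, TRUE)
    sample1 <- sample(0:179, n, TRUE)
    x1 <- wrap_angle_180(ori_imi - ori_C) * pi / 180
    c_prime <- ori_C + dog_predict(x1, list(a = -0.3, w = 2.5))
    x2 <- wrap_angle_180(c_prime - sample1) * pi / 180
    y <- dog_predict(x2, list(a = 1.0, w = 2.2))
    fit <- fit_indirect(x1, ori_C, sample1, y)
    expect_equal(fit$a1, -0.3, tolerance = 1e-3)
    expect_equal(fit$w1, 2.5, tolerance = 1e-3)
    expect_equal(fit$a2, 1.0, tolerance = 1e-3)
    expect_equal(fit$w2, 2.2, tolerance = 1e-3)
    expect_lt(fit$sse, 1e-8)
  })
  expect_error(fit_indirect(1:5 / 10, 1:5, 1:5, 1:5),
               class = "sb_insufficient_data")
})

test_that("compare_models selects the generating model and its deltas are consistent", {
  # direct-model generator: bias on the IMI's angle itself
  withr::with_seed(42, {
    n <- 2000
    ori_C <- sample(0:179, n, TRUE)
    ori_imi <- sample(0:179, n, TRUE)
    sample1 <- sample(0:179, n, TRUE)
    x_imi <- wrap_angle_180(ori_imi - sample1)
    y <- dog_predict(x_imi * pi / 180, list(a = 2, w = 2.24)) + rnorm(n, 0, 4)
    rows <- data.frame(
      x_imi = x_imi,
      x_imi_vs_C = wrap_angle_180(ori_imi - ori_C),
      ori_C = ori_C, sample_1item = sample1,
      residual_error = y - mean(y), included = TRUE
    )
    cmp <- compare_models(rows)
    expect_lt(cmp$aicc_direct, cmp$aicc_null)
    expect_equal(cmp$deltas[["indirect_minus_direct"]] +
                   cmp$deltas[["direct_minus_null"]],
                 cmp$deltas[["indirect_minus_null"]], tolerance = 1e-9)

    # pure noise: the parameter penalty makes the null model win
    rows$residual_error <- withr::with_seed(43, rnorm(n, 0, 8))
    rows$residual_error <- rows$residual_error - mean(rows$residual_error)
    cmp0 <- compare_models(rows)
    expect_equal(cmp0$best, "null")
  })
})
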