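# Circular angle arithmetic, preprocessing, and the CSV trial-pair format.

test_that("wrap_angle_180 maps differences into [-90, 90) with the stated conventions", {
  expect_equal(wrap_angle_180(120 - 90), 30)
  expect_equal(wrap_angle_180(90), -90)
  expect_equal(wrap_angle_180(0 - 170), 10)
  expect_error(wrap_angle_180(NaN), class = "sb_invalid_angle")
  expect_error(wrap_angle_180(Inf), class = "sb_invalid_angle")
})

test_that("wrap_angle_180 is idempotent and 180-periodic", {
  withr::with_seed(4, {
    d <- runif(500, -2000, 2000)
    k <- sample(-10:10, 500, TRUE)
    w <- wrap_angle_180(d)
    expect_true(all(w >= -90 & w < 90))
    expect_equal(wrap_angle_180(w), w)
    expect_equal(wrap_angle_180(d + 180 * k), w)
  })
})

test_that("signed report error wraps across zero and is antisymmetric off the boundary", {
  expect_equal(signed_report_error(92, 90), 2)
  expect_equal(signed_report_error(45, 45), 0)
  expect_equal(signed_report_error(1, 179), 2)
  withr::with_seed(5, {
    a <- runif(200, 0, 180); b <- runif(200, 0, 180)
    e <- signed_report_error(a, b)
    off_boundary <- e != -90
    expect_equal(signed_report_error(b, a)[off_boundary], -e[off_boundary])
  })
})

test_that("the 2-SD exclusion rule matches a hand-computed threshold", {
  rows <- data.frame(error_1item = c(rep(0, 20), 80))
  mu <- mean(rows$error_1item)
  s <- sd(rows$error_1item)
  expect_true(abs(80 - mu) > 2 * s) # the outlier really is past the cut
  expect_true(all(abs(0 - mu) <= 2 * s))
  out <- exclude_outlier_trials(rows)
  expect_equal(out$n_removed, 1)
  expect_equal(which(!out$rows$included), 21L)

  # all identical: SD = 0 and the strict inequality keeps everything
  same <- exclude_outlier_trials(data.frame(error_1item = rep(3, 10)))
  expect_equal(same$n_removed, 0)

  # symmetric +/-5: threshold exceeds every deviation
  pm <- exclude_outlier_trials(data.frame(error_1item = rep(c(5, -5), each = 10)))
  expect_equal(pm$n_removed, 0)

  expect_error(exclude_outlier_trials(data.frame(error_1item = c(1, 2))),
               class = "sb_insufficient_data")
})

test_that("residualization demeans included rows exactly", {
  rows <- data.frame(error_1item = c(5, -5, 3, 3),
                     abc_err_C = NA_real_, included = TRUE)
  out <- residualize_errors(rows)
  expect_equal(mean(out$residual_error), 0, tolerance = 1e-12)
  expect_equal(out$residual_error[1:2], c(3.5, -6.5))

  const <- residualize_errors(data.frame(error_1item = rep(3, 5),
                                         abc_err_C = NA_real_, included = TRUE))
  expect_equal(const$residual_error, rep(0, 5))
})

test_that("exclusion followed by residualization is idempotent on surviving rows", {
  pairs <- make_pairs(n_subjects = 4, seed = 21)
  pp1 <- preprocess_trial_pairs(pairs)
  surv <- pp1$data[pp1$data$included, ]
  expect_equal(mean(surv$residual_error), 0, tolerance = 1e-9)
  # re-run the exclusion + demeaning on the already-cleaned rows
  ex2 <- exclude_outlier_trials(surv)
  res2 <- residualize_errors(ex2$rows)
  again <- res2[res2$included, ]
  expect_equal(nrow(again) + ex2$n_removed, nrow(surv))
  # rows that survive both passes keep their residuals up to the tiny re-demeaning shift
  expect_lt(max(abs(again$residual_error -
                    (again$error_1item - mean(again$error_1item)))), 1e-12)
})

test_that("derived angles follow the attractive-bias sign convention", {
  pairs <- make_pairs(n_subjects = 1, seed = 7)
  i <- which(pairs$cued_item == "A")[1] # respects the location invariants
  pairs$ori_A[i] <- 120L
  pairs$sample_1item[i] <- 90L
  pairs$report_1item[i] <- 92
  d <- derive_trial_pairs(pairs)
  expect_equal(d$x_cued[i], 30)         # 120 vs 90 inducer angle
  expect_equal(d$error_1item[i], 2)     # report 92 of target 90
})

test_that("trial-pair CSV round-trips and rejects malformed tables", {
  pairs <- make_pairs(n_subjects = 2, seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  save_trial_pairs(pairs, f)
  loaded <- load_trial_pairs(f)
  expect_equal(nrow(loaded), nrow(pairs))
  expect_equal(loaded$ori_A, pairs$ori_A)
  expect_equal(loaded$report_1item, pairs$report_1item, tolerance = 1e-6)

  # canonical file: save(load(f)) is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  save_trial_pairs(loaded, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- pairs
  bad$loc_B[3] <- bad$loc_A[3]
  expect_error(save_trial_pairs(bad, f2), "row\\(s\\) 3",
               class = "sb_format_error")

  bad2 <- pairs
  bad2$condition[2] <- "weird"
  expect_error(validate_trial_pairs(bad2), class = "sb_format_error")

  miss <- pairs[, -3]
  expect_error(validate_trial_pairs(miss), "block", class = "sb_format_error")
})

test_that("subject screening removes only extreme-error subjects", {
  pairs <- make_pairs(n_subjects = 6, seed = 13, noise_sd_1item = 6)
  # make one subject grossly noisy
  noisy <- pairs$subject_id == "S001"
  withr::with_seed(2, {
    pairs$report_1item[noisy] <- runif(sum(noisy), 0, 180)
  })
  sc <- screen_subjects(pairs)
  expect_equal(sc$removed_subjects, "S001")
  expect_false(any(sc$pairs$subject_id == "S001"))
})
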