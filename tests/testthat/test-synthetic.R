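# The synthetic experiment generator: design structure and response model.

test_that("the design has the right counts, locations, and counterbalancing", {
  cfg <- simulation_config(n_subjects = 8)
  des <- generate_design(cfg, seed = 50)
  expect_equal(nrow(des), 8 * 6 * 20)
  expect_silent(validate_trial_pairs(des))

  # overlap: C sits at the IMI's location; no_overlap: at a fresh location
  ov <- des[des$condition == "overlap", ]
  imi_loc <- ifelse(ov$cued_item == "A", ov$loc_B, ov$loc_A)
  expect_true(all(ov$loc_C == imi_loc))
  no <- des[des$condition == "no_overlap", ]
  expect_true(all(no$loc_C != no$loc_A & no$loc_C != no$loc_B))

  # three blocks per condition per subject, order alternating across subjects
  tab <- table(des$subject_id, des$condition)
  expect_true(all(tab == 3 * 20))
  first_block <- des[des$block == 1, ]
  expect_equal(unique(first_block$condition[first_block$subject_id == "S001"]),
               "overlap")
  expect_equal(unique(first_block$condition[first_block$subject_id == "S002"]),
               "no_overlap")

  expect_equal(nrow(generate_design(simulation_config(n_subjects = 0))), 0)
})

test_that("orientations are uniform over the integers 0..179", {
  cfg <- simulation_config(n_subjects = 40)
  des <- generate_design(cfg, seed = 51)
  oris <- c(des$ori_A, des$ori_B, des$ori_C, des$sample_1item)
  gof <- chisq.test(table(factor(oris, levels = 0:179)))
  expect_gt(gof$p.value, 0.01)
})

test_that("the response model reduces to known limits", {
  # no noise, no kernels: reports reproduce the samples exactly
  cfg0 <- simulation_config(n_subjects = 2, noise_sd_1item = 0, noise_sd_abc = 0)
  resp0 <- simulate_experiment(cfg0, seed = 52)
  expect_equal(resp0$report_1item, as.numeric(resp0$sample_1item))

  # no noise, one IMI kernel: the error equals the kernel evaluated at x_imi
  cfg1 <- simulation_config(
    n_subjects = 2, noise_sd_1item = 0, noise_sd_abc = 0,
    bias_kernels = list(list(role = "imi", a = 1.25, w = 2.24))
  )
  resp1 <- simulate_experiment(cfg1, seed = 53)
  d <- derive_trial_pairs(resp1)
  expect_equal(d$error_1item,
               dog_predict(d$x_imi * pi / 180, list(a = 1.25, w = 2.24)),
               tolerance = 1e-9)
})

test_that("pure Gaussian noise has the half-normal mean absolute error", {
  cfg <- simulation_config(n_subjects = 96, noise_sd_1item = 10)
  resp <- simulate_experiment(cfg, seed = 54)
  expect_equal(nrow(resp), 11520)
  err <- signed_report_error(resp$report_1item, resp$sample_1item)
  expect_equal(mean(abs(err)), 10 * sqrt(2 / pi), tolerance = 0.025)
})

test_that("an imi_on_C kernel shifts the ABC report of item C", {
  cfg <- simulation_config(
    n_subjects = 2, noise_sd_1item = 0, noise_sd_abc = 0,
    bias_kernels = list(list(role = "imi_on_C", a = -2, w = 2.5))
  )
  resp <- simulate_experiment(cfg, seed = 55)
  cp <- resp[resp$abc_probe == "C", ]
  x <- wrap_angle_180(ifelse(cp$cued_item == "A", cp$ori_B, cp$ori_A) - cp$ori_C)
  expect_equal(signed_report_error(cp$abc_report, cp$ori_C),
               dog_predict(x * pi / 180, list(a = -2, w = 2.5)),
               tolerance = 1e-9)
  # cued-item reports are untouched
  cued <- resp[resp$abc_probe == "cued", ]
  probe_ori <- ifelse(cued$cued_item == "A", cued$ori_A, cued$ori_B)
  expect_equal(cued$abc_report, as.numeric(probe_ori))
})

test_that("config validation rejects unknown kernel roles and bad counts", {
  expect_error(simulation_config(n_subjects = -1), class = "sb_invalid_argument")
  expect_error(simulation_config(2, noise_sd_1item = -3), class = "sb_config_error")
  expect_error(
    simulation_config(2, bias_kernels = list(list(role = "imj", a = 1, w = 2))),
    class = "sb_config_error")
  expect_error(
    simulation_config(2, bias_kernels = list(list(role = "imi", a = 1, w = 99))),
    class = "sb_invalid_params")
  expect_error(
    simulation_config(2, bias_kernels = list(list(role = "imi", a = 1,
                                                  condition = "sometimes", w = 2))),
    class = "sb_config_error")
})
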