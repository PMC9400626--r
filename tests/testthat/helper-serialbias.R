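# Shared fixtures, built in code.

# (x, y) data from a known DoG kernel plus Gaussian noise; x uniform over
# the wrapped orientation-difference range, in radians.
make_xy <- function(n, a = 0, w = 2, noise_sd = 8, seed = NULL) {
  gen <- function() {
    x <- serialbias::wrap_angle_180(sample(0:179, n, TRUE) -
                                    sample(0:179, n, TRUE)) * pi / 180
    y <- serialbias::dog_predict(x, list(a = if (a == 0) 1 else a,
                                         w = w)) * (a != 0)
    list(x = x, y = y + stats::rnorm(n, 0, noise_sd))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# small complete synthetic experiment
make_pairs <- function(n_subjects = 2, seed = 99, ...) {
  cfg <- serialbias::simulation_config(n_subjects = n_subjects, ...)
  serialbias::simulate_experiment(cfg, seed = seed)
}

expect_sb_error <- function(expr, class) {
  expect_error(expr, class = class)
}
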