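# Bootstrap power analysis for the serial-dependence permutation test:
# resample (or generate) datasets of a target size, run the permutation test
# on each, and report the proportion of significant outcomes.

#' Bootstrap power estimate for the serial-dependence permutation test
#'
#' For each of `n_datasets` iterations, draws a dataset of `n_points` rows —
#' either by resampling the supplied `(x, y)` pairs with replacement
#' (retrospective power, or prospective power when `n_points` exceeds the
#' source size) or by calling `generator(n_points)` — runs
#' [permutation_test_serial_bias()] with `n_perm` shuffles, and records the
#' p-value. The power estimate is the proportion of p-values strictly below
#' `alpha`, so with `n_datasets = 100` the resolution is exactly 0.01.
#'
#' @param x,y Source data to resample (angles in radians, residual errors in
#'   degrees). Ignored when `generator` is given.
#' @param generator Optional function `function(n)` returning
#'   `list(x = , y = )`, used instead of resampling.
#' @param n_points Rows per simulated dataset (>= 4).
#' @param n_datasets Number of simulated datasets (default 100).
#' @param n_perm Permutations per test (default 100).
#' @param alpha Significance threshold (default 0.05; strict `<`).
#' @param seed Optional integer seed.
#' @param alternative Passed to [permutation_test_serial_bias()].
#' @return Object of class `power_estimate`: list with `power`, `p_values`,
#'   `n_points`, `n_datasets`, `n_perm`, `alpha`, `seed`.
#' @export
estimate_power <- function(x = NULL, y = NULL, generator = NULL, n_points,
                           n_datasets = 100L, n_perm = 100L, alpha = 0.05,
                           seed = NULL,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n_points <- .check_count(n_points, "n_points", 4L)
  n_datasets <- .check_count(n_datasets, "n_datasets", 1L)
  n_perm <- .check_count(n_perm, "n_perm", 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    .sb_stop("sb_invalid_argument", "alpha must lie strictly between 0 and 1")
  }
  if (is.null(generator)) {
    if (is.null(x) || is.null(y) || length(x) != length(y) || length(x) < 4L) {
      .sb_stop("sb_insufficient_data",
               "supply either a generator or source x/y with >= 4 rows")
    }
    x <- as.numeric(x); y <- as.numeric(y)
  } else if (!is.function(generator)) {
    .sb_stop("sb_invalid_argument", "generator must be a function(n)")
  }

  p_values <- .with_seed(seed, {
    vapply(seq_len(n_datasets), function(i) {
      if (is.null(generator)) {
        idx <- sample.int(length(x), n_points, replace = TRUE)
        xi <- x[idx]; yi <- y[idx]
      } else {
        d <- generator(n_points)
        xi <- d$x; yi <- d$y
      }
      permutation_test_serial_bias(xi, yi, n_perm = n_perm,
                                   alternative = alternative)$p_value
    }, numeric(1))
  })

  structure(list(
    power = mean(p_values < alpha), p_values = p_values,
    n_points = n_points, n_datasets = n_datasets, n_perm = n_perm,
    alpha = alpha, seed = seed
  ), class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Bootstrap power estimate: %.2f (alpha = %g)\n", x$power, x$alpha))
  cat(sprintf("  %d datasets of %d points, %d permutations each\n",
              x$n_datasets, x$n_points, x$n_perm))
  invisible(x)
}
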