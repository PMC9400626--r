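# Permutation and bootstrap inference for the signed peak-to-peak statistic.
#
# All resampled refits reuse the profiled-amplitude structure of fit_dog:
# for a fixed w grid the per-resample sums Sgy(w), Sgg(w), Syy reduce to
# matrix products of the precomputed kernel design matrix with a matrix of
# permuted responses / resample counts / group indicators, followed by the
# same local w refinement as the single fit. Resamples are processed in
# chunks to bound memory.

.SB_CHUNK <- 250L

# batch fit from chunked sums; Y columns are handled by prof_factory(b)
.batch_p2p <- function(SgY, SggM, Syy, wg, prof_factory,
                       a_bounds = .DOG_A_BOUNDS) {
  B <- ncol(SgY)
  p2p <- numeric(B)
  for (b in seq_len(B)) {
    sgg <- if (is.matrix(SggM)) SggM[, b] else SggM
    best <- .dog_fit_core(SgY[, b], sgg, Syy[b], wg, prof_factory(b), a_bounds)
    p2p[b] <- .p2p_closed(best$a, best$w)
  }
  p2p
}

.perm_pvalue <- function(obs, null, alternative) {
  switch(alternative,
    two.sided = mean(abs(null) >= abs(obs)),
    greater   = mean(null >= obs),
    less      = mean(null <= obs)
  )
}

#' Permutation test for serial-dependence bias
#'
#' Fits the DoG kernel to the observed (x, y) pairs, then builds a null
#' distribution of the signed peak-to-peak statistic by shuffling the x
#' labels against the fixed responses and refitting, `n_perm` times. The
#' p-value is the plain proportion of null statistics at least as extreme as
#' the observed one (two-sided on `|p2p|` by default; one-sided alternatives
#' are available).
#'
#' @param x Relative inducer angles in radians.
#' @param y Residual report errors in degrees.
#' @param n_perm Number of label shuffles (>= 1).
#' @param n_boot If > 0, additionally compute a bootstrap percentile
#'   confidence interval for the peak-to-peak statistic (see
#'   [bootstrap_p2p_ci()]).
#' @param level Confidence level for the bootstrap interval.
#' @param seed Optional integer seed; the caller's RNG stream is preserved.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return An object of class `bias_test`: list with `fit` (the observed
#'   [fit_dog()] result), `p2p`, `p_value`, `null_p2p` (length `n_perm`),
#'   `ci_low`/`ci_high` (`NA` unless `n_boot > 0`), `n`, `n_perm`, `n_boot`,
#'   `seed`, `alternative`.
#' @export
permutation_test_serial_bias <- function(x, y, n_perm = 1000L, n_boot = 0L,
                                         level = 0.95, seed = NULL,
                                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n_perm <- .check_count(n_perm, "n_perm", 1L)
  if (n_boot != 0) n_boot <- .check_count(n_boot, "n_boot", 1L)
  fit <- fit_dog(x, y)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  wg <- .dog_wgrid()
  G <- .dog_G(x, wg)
  sgg <- colSums(G * G)
  syy <- sum(y * y)

  res <- .with_seed(seed, {
    null_p2p <- numeric(n_perm)
    done <- 0L
    while (done < n_perm) {
      m <- min(.SB_CHUNK, n_perm - done)
      # shuffling x against fixed y is the same fit as permuting y against x
      Y <- vapply(seq_len(m), function(b) y[sample.int(n)], numeric(n))
      SgY <- crossprod(G, Y)
      null_p2p[done + seq_len(m)] <- .batch_p2p(
        SgY, sgg, rep(syy, m), wg,
        function(b) .dog_profile(x, Y[, b])
      )
      done <- done + m
    }
    ci <- if (n_boot > 0) {
      .bootstrap_p2p_core(x, y, n_boot, level, G, wg)
    } else {
      list(ci_low = NA_real_, ci_high = NA_real_)
    }
    list(null_p2p = null_p2p, ci = ci)
  })

  structure(list(
    fit = fit, p2p = fit$p2p,
    p_value = .perm_pvalue(fit$p2p, res$null_p2p, alternative),
    null_p2p = res$null_p2p,
    ci_low = res$ci$ci_low, ci_high = res$ci$ci_high,
    n = n, n_perm = n_perm, n_boot = n_boot, seed = seed,
    alternative = alternative
  ), class = "bias_test")
}

# bootstrap core running on the current RNG stream; G/wg precomputed
.bootstrap_p2p_core <- function(x, y, n_boot, level, G, wg) {
  n <- length(x)
  G2 <- G * G
  H <- G * y
  y2 <- y * y
  boot_p2p <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    m <- min(.SB_CHUNK, n_boot - done)
    C <- vapply(seq_len(m),
                function(b) tabulate(sample.int(n, n, replace = TRUE), n),
                numeric(n))
    SgY <- crossprod(H, C)
    SggM <- crossprod(G2, C)
    Syy <- as.vector(crossprod(C, y2))
    boot_p2p[done + seq_len(m)] <- .batch_p2p(
      SgY, SggM, Syy, wg,
      function(b) .dog_profile(x, y, wts = C[, b])
    )
    done <- done + m
  }
  qs <- stats::quantile(boot_p2p, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], boot_p2p = boot_p2p)
}

#' Bootstrap percentile confidence interval for the peak-to-peak statistic
#'
#' Resamples the (x, y) pairs with replacement `n_boot` times, refits the DoG
#' kernel to each resample, and returns the percentile interval of the
#' resulting peak-to-peak distribution (2.5th and 97.5th percentiles at the
#' default level of 0.95).
#'
#' @inheritParams permutation_test_serial_bias
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @return Object of class `p2p_ci`: list with `ci_low`, `ci_high`, `level`,
#'   `n_boot`, and the full `boot_p2p` distribution.
#' @export
bootstrap_p2p_ci <- function(x, y, n_boot = 1000L, level = 0.95, seed = NULL) {
  n_boot <- .check_count(n_boot, "n_boot", 1L)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    .sb_stop("sb_invalid_argument", "level must lie strictly between 0 and 1")
  }
  fit <- fit_dog(x, y) # validates inputs
  x <- as.numeric(x); y <- as.numeric(y)
  wg <- .dog_wgrid()
  G <- .dog_G(x, wg)
  core <- .with_seed(seed, .bootstrap_p2p_core(x, y, n_boot, level, G, wg))
  structure(c(core, list(level = level, n_boot = n_boot, p2p = fit$p2p,
                         seed = seed)),
            class = "p2p_ci")
}

#' Permutation test for a between-condition difference in bias
#'
#' Tests whether the signed peak-to-peak statistic differs between two
#' conditions. The observed statistic is `p2p(A) - p2p(B)`; the null is built
#' by randomly relabeling the condition assignment of the pooled data points
#' (preserving group sizes) and recomputing the difference, `n_perm` times.
#'
#' @param x_a,y_a Angles (radians) and residual errors (degrees) for
#'   condition A.
#' @param x_b,y_b Same for condition B.
#' @inheritParams permutation_test_serial_bias
#' @return Object of class `condition_diff_test`: list with `difference`
#'   (degrees), `p_value`, `p2p_a`, `p2p_b`, `null_diff`, `n_a`, `n_b`,
#'   `n_perm`, `seed`, `alternative`.
#' @export
permutation_test_condition_difference <- function(x_a, y_a, x_b, y_b,
                                                  n_perm = 1000L, seed = NULL,
                                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n_perm <- .check_count(n_perm, "n_perm", 1L)
  if (length(x_a) < 4L || length(x_b) < 4L) {
    .sb_stop("sb_insufficient_data",
             "each condition needs at least 4 rows (got %d and %d)",
             length(x_a), length(x_b))
  }
  fit_a <- fit_dog(x_a, y_a)
  fit_b <- fit_dog(x_b, y_b)
  observed <- fit_a$p2p - fit_b$p2p

  x <- c(as.numeric(x_a), as.numeric(x_b))
  y <- c(as.numeric(y_a), as.numeric(y_b))
  n <- length(x)
  n_a <- length(x_a)
  wg <- .dog_wgrid()
  G <- .dog_G(x, wg)
  G2 <- G * G
  H <- G * y
  y2 <- y * y
  sgy_tot <- as.vector(crossprod(H, rep(1, n)))
  sgg_tot <- colSums(G2)
  syy_tot <- sum(y2)

  null_diff <- .with_seed(seed, {
    out <- numeric(n_perm)
    done <- 0L
    while (done < n_perm) {
      m <- min(.SB_CHUNK, n_perm - done)
      M <- vapply(seq_len(m), function(b) {
        ind <- numeric(n); ind[sample.int(n, n_a)] <- 1; ind
      }, numeric(n))
      SgA <- crossprod(H, M)
      SggA <- crossprod(G2, M)
      SyyA <- as.vector(crossprod(M, y2))
      p2p_a <- .batch_p2p(SgA, SggA, SyyA, wg,
                          function(b) .dog_profile(x, y, wts = M[, b]))
      p2p_b <- .batch_p2p(sgy_tot - SgA, sgg_tot - SggA, syy_tot - SyyA, wg,
                          function(b) .dog_profile(x, y, wts = 1 - M[, b]))
      out[done + seq_len(m)] <- p2p_a - p2p_b
      done <- done + m
    }
    out
  })

  structure(list(
    difference = observed,
    p_value = .perm_pvalue(observed, null_diff, alternative),
    p2p_a = fit_a$p2p, p2p_b = fit_b$p2p,
    fit_a = fit_a, fit_b = fit_b,
    null_diff = null_diff,
    n_a = n_a, n_b = length(x_b), n_perm = n_perm, seed = seed,
    alternative = alternative
  ), class = "condition_diff_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat("Serial-dependence permutation test\n")
  cat("  peak-to-peak:", format(x$p2p, digits = 4), "deg (a =",
      format(x$fit$a, digits = 4), ", w =", format(x$fit$w, digits = 4), ")\n")
  cat("  p =", format(x$p_value, digits = 4), sprintf("(%s, %d permutations)",
      x$alternative, x$n_perm), "\n")
  if (!is.na(x$ci_low)) {
    cat("  bootstrap 95% CI: [", format(x$ci_low, digits = 4), ",",
        format(x$ci_high, digits = 4), "]\n")
  }
  cat("  n =", x$n, "\n")
  invisible(x)
}

#' @export
print.condition_diff_test <- function(x, ...) {
  cat("Condition-difference permutation test\n")
  cat("  p2p(A) =", format(x$p2p_a, digits = 4), "deg, p2p(B) =",
      format(x$p2p_b, digits = 4), "deg\n")
  cat("  difference =", format(x$difference, digits = 4), "deg, p =",
      format(x$p_value, digits = 4), sprintf("(%d permutations)", x$n_perm), "\n")
  invisible(x)
}
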