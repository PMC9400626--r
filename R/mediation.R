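# Direct-influence, indirect-influence (two-stage), and null models of the
# IMI's effect on 1-item recall, compared by finite-sample-corrected AIC.

#' Corrected Akaike Information Criterion for a least-squares fit
#'
#' Gaussian-likelihood AICc for a model with `k` mean-function parameters fit
#' by least squares: \eqn{n \ln(SSE/n) + 2k + 2k(k+1)/(n-k-1)}. With
#' `count_sigma = TRUE` the error variance is counted as an extra parameter
#' (`k + 1`), the other common convention.
#'
#' @param sse Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param k Number of mean-function parameters.
#' @param count_sigma Count the noise variance as a parameter (default
#'   `FALSE`).
#' @return The AICc value.
#' @examples
#' aicc(sse = 10, n = 10, k = 2) # 4 + 12/7
#' @export
aicc <- function(sse, n, k, count_sigma = FALSE) {
  if (!is.numeric(sse) || length(sse) != 1L || !is.finite(sse) || sse <= 0) {
    .sb_stop("sb_invalid_argument", "sse must be a single positive number")
  }
  n <- .check_count(n, "n", 1L)
  k <- .check_count(k, "k", 0L)
  keff <- if (count_sigma) k + 1L else k
  if (n <= keff + 1L) {
    .sb_stop("sb_invalid_argument",
             "AICc requires n > k + 1 (n = %d, effective k = %d)", n, keff)
  }
  n * log(sse / n) + 2 * keff + 2 * keff * (keff + 1) / (n - keff - 1)
}

# SSE of the indirect model at explicit parameters. Stage 1 shifts item C's
# stored orientation by a DoG of the IMI-vs-C angle; stage 2 predicts the
# 1-item residual error from the shifted item's angle relative to the sample.
.indirect_sse <- function(theta, x_imi_vs_C, ori_C, sample_1item, y) {
  c_prime <- ori_C + theta[1] * .dog_g(x_imi_vs_C, theta[2])
  x2 <- .deg2rad(wrap_angle_180(c_prime - sample_1item))
  resid <- y - theta[3] * .dog_g(x2, theta[4])
  sum(resid * resid)
}

# Stage-2-profiled objective: for fixed (a1, w1) the optimal stage-2 kernel
# is an ordinary DoG fit, solved on a w grid with the amplitude profiled out.
.indirect_profile_sse <- function(a1w1, x_imi_vs_C, ori_C, sample_1item, y,
                                  wg) {
  c_prime <- ori_C + a1w1[1] * .dog_g(x_imi_vs_C, a1w1[2])
  x2 <- .deg2rad(wrap_angle_180(c_prime - sample_1item))
  G <- .dog_G(x2, wg)
  sgy <- as.vector(crossprod(G, y))
  sgg <- colSums(G * G)
  a <- ifelse(sgg > 0, sgy / sgg, 0)
  a <- pmin(pmax(a, .DOG_A_BOUNDS[1]), .DOG_A_BOUNDS[2])
  sse <- sum(y * y) - 2 * a * sgy + a * a * sgg
  k <- which.min(sse)
  list(sse = sse[k], a2 = a[k], w2 = wg[k])
}

#' Fit the indirect-influence (two-stage) model
#'
#' Two chained DoG kernels: stage 1 estimates the stored orientation of item
#' C as biased by the IMI, \eqn{C' = C + \mathrm{DoG}(x_{imi};a_1,w_1)};
#' stage 2 predicts the residual 1-item recall error from the angle of
#' \eqn{C'} relative to the 1-item sample, \eqn{\hat y =
#' \mathrm{DoG}(\mathrm{wrap}(C' - \mathrm{sample}); a_2, w_2)}. All four
#' parameters are optimized jointly against \eqn{\sum (y - \hat y)^2}:
#' a deterministic multi-start bounded search over \eqn{(a_1, w_1)} with the
#' stage-2 kernel profiled out, followed by a joint four-parameter polish.
#'
#' @param x_imi_vs_C Angle of the IMI relative to item C, radians.
#' @param ori_C True orientation of item C, degrees.
#' @param sample_1item Orientation of the linked 1-item sample, degrees.
#' @param y Residual 1-item report error, degrees.
#' @return Object of class `indirect_fit`: list with `a1`, `w1`, `a2`, `w2`,
#'   `sse`, `n`, `converged`.
#' @export
fit_indirect <- function(x_imi_vs_C, ori_C, sample_1item, y) {
  n <- length(y)
  lens <- c(length(x_imi_vs_C), length(ori_C), length(sample_1item))
  if (any(lens != n)) {
    .sb_stop("sb_invalid_argument", "all input sequences must be aligned")
  }
  if (n < 8L) {
    .sb_stop("sb_insufficient_data",
             "indirect fit needs at least 8 rows (got %d)", n)
  }
  x_imi_vs_C <- as.numeric(x_imi_vs_C)
  ori_C <- as.numeric(ori_C)
  sample_1item <- as.numeric(sample_1item)
  y <- as.numeric(y)

  wg_search <- .dog_wgrid(n_w = 61L)
  obj <- function(p) {
    .indirect_profile_sse(p, x_imi_vs_C, ori_C, sample_1item, y, wg_search)$sse
  }
  starts <- expand.grid(a1 = c(-1, 0, 1), w1 = c(1, 2.5, 8))
  lower2 <- c(.DOG_A_BOUNDS[1], .DOG_W_BOUNDS[1])
  upper2 <- c(.DOG_A_BOUNDS[2], .DOG_W_BOUNDS[2])
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- stats::optim(as.numeric(starts[s, ]), obj, method = "L-BFGS-B",
                        lower = lower2, upper = upper2,
                        control = list(maxit = 200L))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  stage2 <- .indirect_profile_sse(best$par, x_imi_vs_C, ori_C, sample_1item,
                                  y, .dog_wgrid(n_w = 251L))
  theta0 <- c(best$par[1], best$par[2], stage2$a2, stage2$w2)
  lower4 <- c(.DOG_A_BOUNDS[1], .DOG_W_BOUNDS[1], .DOG_A_BOUNDS[1], .DOG_W_BOUNDS[1])
  upper4 <- c(.DOG_A_BOUNDS[2], .DOG_W_BOUNDS[2], .DOG_A_BOUNDS[2], .DOG_W_BOUNDS[2])
  polish <- stats::optim(theta0, .indirect_sse, method = "L-BFGS-B",
                         lower = lower4, upper = upper4,
                         control = list(maxit = 500L, factr = 1e4),
                         x_imi_vs_C = x_imi_vs_C, ori_C = ori_C,
                         sample_1item = sample_1item, y = y)
  theta <- if (polish$value <= stage2$sse) polish$par else theta0
  sse <- min(polish$value, stage2$sse)
  structure(list(
    a1 = theta[1], w1 = theta[2], a2 = theta[3], w2 = theta[4],
    sse = sse, n = n,
    converged = polish$convergence == 0L
  ), class = "indirect_fit")
}

#' @export
print.indirect_fit <- function(x, ...) {
  cat("Indirect-influence (two-stage DoG) fit\n")
  cat(sprintf("  stage 1 (IMI -> item C): a1 = %.4g, w1 = %.4g\n", x$a1, x$w1))
  cat(sprintf("  stage 2 (C' -> recall) : a2 = %.4g, w2 = %.4g\n", x$a2, x$w2))
  cat(sprintf("  SSE = %.6g on n = %d\n", x$sse, x$n))
  invisible(x)
}

#' Compare direct, indirect, and null models of the IMI's influence by AICc
#'
#' Fits, on the preprocessed rows of one condition, three accounts of how the
#' irrelevant memory item (IMI) affects the linked 1-item recall: the
#' *direct* model (a single DoG of the IMI's angle relative to the 1-item
#' sample, k = 2), the *indirect* model (IMI biases item C, which then biases
#' recall; [fit_indirect()], k = 4), and the *null* model (\eqn{\hat y = 0},
#' k = 0). Returns the three AICc values, all pairwise deltas, and the
#' winner.
#'
#' @param rows Preprocessed derived table for one condition (included rows
#'   with `residual_error`, `x_imi`, `x_imi_vs_C`, `ori_C`, `sample_1item`).
#' @param count_sigma Passed to [aicc()].
#' @return Object of class `model_comparison`: list with `aicc_direct`,
#'   `aicc_indirect`, `aicc_null`, `deltas` (named vector of pairwise
#'   differences), `best`, and the underlying fits.
#' @export
compare_models <- function(rows, count_sigma = FALSE) {
  need <- c("x_imi", "x_imi_vs_C", "ori_C", "sample_1item", "residual_error",
            "included")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    .sb_stop("sb_invalid_argument", "rows is missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  rows <- rows[rows$included & !is.na(rows$residual_error), , drop = FALSE]
  y <- rows$residual_error
  n <- length(y)
  direct <- fit_dog(.deg2rad(rows$x_imi), y)
  indirect <- fit_indirect(.deg2rad(rows$x_imi_vs_C), rows$ori_C,
                           rows$sample_1item, y)
  sse_null <- sum(y * y)
  aicc_direct <- aicc(direct$sse, n, 2L, count_sigma)
  aicc_indirect <- aicc(indirect$sse, n, 4L, count_sigma)
  aicc_null <- aicc(sse_null, n, 0L, count_sigma)
  vals <- c(direct = aicc_direct, indirect = aicc_indirect, null = aicc_null)
  deltas <- c(
    indirect_minus_direct = aicc_indirect - aicc_direct,
    direct_minus_null = aicc_direct - aicc_null,
    indirect_minus_null = aicc_indirect - aicc_null
  )
  structure(list(
    aicc_direct = aicc_direct, aicc_indirect = aicc_indirect,
    aicc_null = aicc_null, deltas = deltas,
    best = names(vals)[which.min(vals)],
    fit_direct = direct, fit_indirect = indirect, sse_null = sse_null,
    n = n
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (AICc), n =", x$n, "\n")
  cat(sprintf("  direct  : %.3f\n  indirect: %.3f\n  null    : %.3f\n",
              x$aicc_direct, x$aicc_indirect, x$aicc_null))
  cat("  best:", x$best, "\n")
  invisible(x)
}
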