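#' Wrap an angular difference into the orientation interval [-90, 90)
#'
#' Orientation stimuli live on a 180-degree circle (a Gabor rotated by 180
#' degrees is identical to the original), so differences between orientations
#' are only defined modulo 180. `wrap_angle_180()` maps any real angular
#' difference to the unique equivalent value in the half-open interval
#' \eqn{[-90, 90)}; the boundary value +90 maps to -90.
#'
#' @param delta Numeric vector of angular differences in degrees (any real
#'   values).
#' @return Numeric vector of the same length, each element in \eqn{[-90, 90)}
#'   and congruent to the input modulo 180.
#' @examples
#' wrap_angle_180(120 - 90) # +30
#' wrap_angle_180(90)       # -90 (boundary convention)
#' wrap_angle_180(0 - 170)  # +10
#' @export
wrap_angle_180 <- function(delta) {
  if (!is.numeric(delta) || anyNA(delta) || any(!is.finite(delta))) {
    .sb_stop("sb_invalid_angle", "angles must be finite numeric values")
  }
  ((delta + 90) %% 180) - 90
}

#' Signed report error on the 180-degree orientation circle
#'
#' The signed deviation of a reproduction report from the target orientation,
#' wrapped to \eqn{[-90, 90)}. A report of 92 degrees for a 90-degree target
#' gives +2; the sign convention follows [wrap_angle_180()], so with
#' `x = wrap_angle_180(inducer - target)` an attractive serial bias produces
#' errors with the same sign as `x` near zero.
#'
#' @param report Numeric vector of reported orientations, degrees.
#' @param target Numeric vector of true target orientations, degrees.
#' @return Signed error in degrees, in \eqn{[-90, 90)}.
#' @examples
#' signed_report_error(92, 90)  # +2
#' signed_report_error(1, 179)  # +2 (wraps across 0)
#' @export
signed_report_error <- function(report, target) {
  wrap_angle_180(report - target)
}

# degrees -> radians for the DoG x-axis
.deg2rad <- function(deg) deg * pi / 180
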