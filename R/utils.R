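# Shared helpers: axial (180-degree periodic) angle arithmetic and input checks.
#
# Angle convention used throughout the package: degrees on [0, 180),
# 0 deg = horizontal, pointing right; positive angles counterclockwise.
# Reported retardance axes refer to the FAST axis (see `mueller_convention()`).

DEG2RAD <- pi / 180

#' Reduce angles to the axial range [0, 180)
#'
#' Orientations of fibers and polarization axes are axial quantities: an
#' angle and that angle plus 180 degrees describe the same axis.
#'
#' @param a Numeric vector of angles in degrees.
#' @return Angles reduced modulo 180, in `[0, 180)`.
#' @export
axial_mod <- function(a) a %% 180

#' Signed minimal axial difference between two orientations
#'
#' @param a,b Angles in degrees (any real values).
#' @return Signed difference `a - b` reduced to `(-90, 90]` degrees.
#' @export
axial_diff <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Absolute axial distance between two orientations
#'
#' @inheritParams axial_diff
#' @return Distance in degrees, in `[0, 90]`.
#' @export
axial_dist <- function(a, b) abs(axial_diff(a, b))

#' Circular mean of axial data
#'
#' Computes the mean orientation of 180-degree periodic data by averaging
#' in doubled-angle space, optionally weighted.
#'
#' @param a Angles in degrees; `NA` entries are dropped.
#' @param w Optional non-negative weights, recycled to `length(a)`.
#' @return Mean orientation in degrees on `[0, 180)`, or `NA` if no valid
#'   input remains.
#' @export
axial_mean <- function(a, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  w <- rep_len(w, length(a))
  ok <- !is.na(a) & !is.na(w)
  if (!any(ok)) return(NA_real_)
  a <- a[ok]; w <- w[ok]
  s <- sum(w * sin(2 * a * DEG2RAD))
  c_ <- sum(w * cos(2 * a * DEG2RAD))
  if (abs(s) < 1e-15 && abs(c_) < 1e-15) return(NA_real_)
  axial_mod(0.5 * atan2(s, c_) / DEG2RAD)
}

stop_invalid <- function(...) {
  stop(structure(class = c("muellerpli_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stop_invalid("`", name, "` must be finite")
  invisible(x)
}

check_range <- function(x, lo, hi, name) {
  check_finite(x, name)
  if (any(x < lo | x > hi)) {
    stop_invalid("`", name, "` must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}
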