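# Correction of the inverse-cosine phase-wrapping artifact.
#
# The Lu-Chipman retardance R = acos(tr(M_ret)/2 - 1) is bounded to [0, pi];
# when the true retardance grows past pi the recovered value is mirrored
# around pi and the recovered axis jumps by 90 degrees.  The wrapped portion
# of a profile or map is located through that 90-degree axis discontinuity,
# then corrected by taking 2*pi - R (branch "around_pi") or by negating the
# sign (branch "around_zero", magnitude preserved) and shifting the affected
# angles by +90 degrees.  Branch selection follows the convention that mean
# retardance decreases with imaging wavelength.

insufficient_data <- function(msg) {
  structure(class = c("muellerpli_insufficient_data", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Construct a wrap mask
#'
#' @param flags Logical vector or matrix marking wrapped entries.
#' @param branch `"around_pi"`, `"around_zero"`, or `NA` (undecided).
#' @param provenance `"auto"` (detected) or `"user"`.
#' @return An object of class `wrap_mask`.
#' @export
wrap_mask <- function(flags, branch = NA_character_, provenance = "user") {
  if (!is.logical(flags)) stop_invalid("`flags` must be logical")
  if (!is.na(branch) && !branch %in% c("around_pi", "around_zero")) {
    stop_invalid("`branch` must be \"around_pi\", \"around_zero\" or NA")
  }
  structure(list(flags = flags, branch = branch, provenance = provenance),
            class = "wrap_mask")
}

# 1-D scan: toggle the wrapped state at every axial jump near the target
detect_1d <- function(a, jump_target, tolerance) {
  n <- length(a)
  flags <- rep(FALSE, n)
  state <- FALSE
  last <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(a[i])) { flags[i] <- state; next }
    if (!is.na(last)) {
      d <- axial_dist(a[i], last)
      if (abs(d - jump_target) <= tolerance) state <- !state
    }
    flags[i] <- state
    last <- a[i]
  }
  flags
}

#' Detect phase-wrapped regions from axis-angle discontinuities
#'
#' Scans an angle profile (vector) or map (matrix, scanned row by row) for
#' axial jumps of about `jump_target` degrees and flags the region beyond
#' each jump, toggling at every further jump.  Jumps are measured with
#' axial (180-degree periodic) distance; entries exactly at a discontinuity
#' are assigned to the flagged side.
#'
#' @param angle_data Angles in degrees on `[0, 180)`; `NA` = undefined.
#' @param jump_target Expected jump magnitude in degrees (default 90, the
#'   wrapping artifact's signature).
#' @param tolerance Acceptance window around `jump_target` in degrees
#'   (default 20).
#' @return A `wrap_mask` with undecided branch and provenance `"auto"`.
#' @export
detect_wrapped_regions <- function(angle_data, jump_target = 90,
                                   tolerance = 20) {
  if (sum(!is.na(angle_data)) < 2) {
    stop(insufficient_data("need at least 2 valid angle samples"))
  }
  if (is.matrix(angle_data)) {
    flags <- t(apply(angle_data, 1, detect_1d, jump_target, tolerance))
    dim(flags) <- dim(angle_data)
  } else {
    flags <- detect_1d(as.numeric(angle_data), jump_target, tolerance)
  }
  wrap_mask(flags, branch = NA_character_, provenance = "auto")
}

#' Apply the phase-unwrapping correction
#'
#' On flagged entries, corrects the retardance according to the chosen
#' branch -- `2*pi - R` when the data were mirrored around pi, or a sign
#' annotation with preserved magnitude when mirrored around zero -- and
#' shifts the angle by +90 degrees (mod 180).  Unflagged entries pass
#' through bit-identical.  Corrected outputs carry an `unwrap_corrected`
#' attribute and a second application is refused.
#'
#' @param retardance Numeric vector/matrix of retardance in radians; flagged
#'   entries must lie in `[0, pi]`.
#' @param angle Matching vector/matrix of angles in degrees (`NA` allowed).
#' @param mask A `wrap_mask` with matching shape.
#' @param branch Branch override; required when `mask$branch` is `NA`.
#' @return A list with `retardance`, `angle`, `sign` (+1/-1 per entry, -1
#'   only on flagged entries under the around_zero branch), and `branch`.
#' @export
apply_unwrap <- function(retardance, angle, mask, branch = NULL) {
  stopifnot(inherits(mask, "wrap_mask"))
  if (isTRUE(attr(retardance, "unwrap_corrected"))) {
    stop_invalid("input already unwrap-corrected; refusing double correction")
  }
  br <- if (!is.null(branch)) branch else mask$branch
  if (is.na(br) || !br %in% c("around_pi", "around_zero")) {
    stop_invalid("unwrap branch required (around_pi or around_zero)")
  }
  f <- mask$flags
  if (length(f) != length(retardance) || length(f) != length(angle)) {
    stop_invalid("mask shape does not match data")
  }
  fl <- which(f)
  rr <- retardance
  sgn <- array(1, dim = dim(retardance) %||% length(retardance))
  if (length(fl)) {
    if (any(rr[fl] < -1e-12 | rr[fl] > pi + 1e-12, na.rm = TRUE)) {
      stop_invalid("flagged retardance must lie in [0, pi] before unwrapping")
    }
    if (br == "around_pi") {
      rr[fl] <- 2 * pi - rr[fl]
    } else {
      sgn[fl] <- -1  # magnitude preserved, sign annotated
    }
  }
  aa <- angle
  aa[fl] <- (angle[fl] + 90) %% 180
  attr(rr, "unwrap_corrected") <- TRUE
  list(retardance = rr, angle = aa, sign = sgn, branch = br)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the unwrapping branch from wavelength trends
#'
#' Mean retardance is expected to decrease with imaging wavelength; the
#' branch whose corrected per-wavelength ROI means best follow that trend
#' (fewest monotonicity violations, i.e. fewest non-decreasing steps) is
#' selected.  A tie selects `around_pi` with the ambiguity flag set; if no
#' candidate is monotone the decision is refused (`branch = NA`) and the
#' ambiguity flag is set.
#'
#' @param wavelength Wavelengths in nm.
#' @param mean_around_pi,mean_around_zero Mean ROI retardance (radians) per
#'   wavelength under each candidate correction; `NA` = unavailable.
#' @return A list with `branch` (`"around_pi"`, `"around_zero"` or `NA`),
#'   `ambiguous` (logical) and `violations` (named integer vector).
#' @export
select_branch <- function(wavelength, mean_around_pi, mean_around_zero) {
  stopifnot(length(wavelength) == length(mean_around_pi),
            length(wavelength) == length(mean_around_zero))
  count_viol <- function(m) {
    ok <- !is.na(m)
    if (sum(ok) < 2) return(NA_integer_)
    d <- diff(m[ok][order(wavelength[ok])])
    sum(d >= 0)
  }
  v <- c(around_pi = count_viol(mean_around_pi),
         around_zero = count_viol(mean_around_zero))
  if (all(is.na(v))) stop(insufficient_data("no branch has >= 2 valid means"))
  monotone <- !is.na(v) & v == 0
  if (sum(monotone) == 1) {
    return(list(branch = names(v)[monotone], ambiguous = FALSE,
                violations = v))
  }
  if (sum(monotone) == 2) {
    return(list(branch = "around_pi", ambiguous = TRUE, violations = v))
  }
  list(branch = NA_character_, ambiguous = TRUE, violations = v)
}

#' Unwrap the retardance and retardance-angle planes of a map set
#'
#' Convenience wrapper applying [apply_unwrap()] to a `polarization_maps`
#' object; refuses maps already marked corrected.
#'
#' @param maps A `polarization_maps` object.
#' @param mask A `wrap_mask` matching the map shape.
#' @param branch Branch override (see [apply_unwrap()]).
#' @return The corrected `polarization_maps` (with `corrected = TRUE`).
#' @export
unwrap_polarization_maps <- function(maps, mask, branch = NULL) {
  stopifnot(inherits(maps, "polarization_maps"))
  if (isTRUE(maps$corrected)) {
    stop_invalid("maps already unwrap-corrected; refusing double correction")
  }
  u <- apply_unwrap(maps$retardance, maps$retardance_angle, mask, branch)
  ret <- u$retardance
  attr(ret, "unwrap_corrected") <- NULL
  polarization_maps(ret, u$angle, maps$diattenuation,
                    maps$diattenuation_angle, maps$depolarization,
                    maps$wavelength, maps$validity, corrected = TRUE)
}
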