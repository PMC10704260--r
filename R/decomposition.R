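# Lu-Chipman polar decomposition and pixelwise polarization-property maps.
#
# A measured Mueller matrix M is factored as M = M_depol %*% M_ret %*% M_diatt
# (depolarizer times retarder times diattenuator, in that order).  Scalar
# summaries follow the standard Lu-Chipman definitions:
#   retardance       R = acos(tr(M_ret)/2 - 1), in [0, pi]
#   diattenuation    D = ||first row|| / m00, in [0, 1]
#   depolarization   Delta = 1 - |tr(M_depol) - 1| / 3, in [0, 1]
# The inverse cosine bounds R to [0, pi]; true retardance beyond pi is folded
# back ("phase wrapping") with a 90-degree flip of the recovered axis.  The
# phase_unwrap module corrects that artifact downstream.

decomposition_failure <- function(msg) {
  structure(class = c("muellerpli_decomposition_failure", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factors `M` into depolarizer, retarder and diattenuator Mueller matrices
#' such that `M = M_depol %*% M_ret %*% M_diatt`.
#'
#' @param M A finite 4x4 Mueller matrix with `m00 > 0`.
#' @return A list of class `lu_chipman` with components `M_depol`, `M_ret`,
#'   `M_diatt`, the maximum absolute reconstruction `residual`, and a
#'   `degenerate` flag set when the depolarizer eigenstructure had to be
#'   regularized (near-zero eigenvalues clamped at 1e-12).
#' @seealso [retardance_params()], [diattenuation_params()],
#'   [depolarization_power()], [decompose_stack()]
#' @export
lu_chipman_decompose <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(4, 4)) || !all(is.finite(M))) {
    stop(decomposition_failure("input is not a finite 4x4 matrix"))
  }
  m00 <- M[1, 1]
  if (m00 <= 0) stop(decomposition_failure("m00 must be positive"))
  Mn <- M / m00

  Dvec <- Mn[1, 2:4]
  D <- sqrt(sum(Dvec^2))
  if (D >= 1) stop(decomposition_failure("diattenuation magnitude >= 1"))

  k <- sqrt(1 - D^2)
  mD <- k * diag(3)
  if (D > 0) {
    Dhat <- Dvec / D
    mD <- mD + (1 - k) * (Dhat %o% Dhat)
  }
  MD <- rbind(c(1, Dvec), cbind(Dvec, mD))

  Mp <- Mn %*% solve(MD)
  Pdelta <- Mp[2:4, 1]
  mp <- Mp[2:4, 2:4]

  G <- mp %*% t(mp)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  degenerate <- any(lam < 1e-12)
  lam <- pmax(lam, 1e-12)
  sq <- sqrt(lam)
  s <- if (det(mp) < 0) -1 else 1

  A <- G + (sq[1] * sq[2] + sq[2] * sq[3] + sq[3] * sq[1]) * diag(3)
  B <- (sq[1] + sq[2] + sq[3]) * G + sq[1] * sq[2] * sq[3] * diag(3)
  mDelta <- s * solve(A, B)
  mR <- solve(mDelta, mp)

  Mdepol <- unname(rbind(c(1, 0, 0, 0), cbind(Pdelta, mDelta)))
  Mret <- unname(rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), mR)))
  Mdiatt <- unname(m00 * MD)

  recon <- Mdepol %*% Mret %*% Mdiatt
  structure(list(M_depol = Mdepol, M_ret = Mret, M_diatt = Mdiatt,
                 residual = max(abs(recon - M)), degenerate = degenerate),
            class = "lu_chipman")
}

#' Retardance magnitude and axis from a retarder factor
#'
#' Applies the inverse-cosine retardance formula `R = acos(tr(M_ret)/2 - 1)`
#' and recovers the linear retardance axis from the antisymmetric part of the
#' 3x3 block.  `R` is intrinsically bounded to `[0, pi]`: true retardance
#' above pi is mirrored back and the recovered axis flips by 90 degrees (the
#' phase-wrapping artifact corrected by the phase_unwrap module).
#'
#' @param M_ret A retarder Mueller matrix (3x3 block orthogonal).
#' @param axis_tol Retardance below which the axis is reported as `NA`
#'   (undefined orientation).
#' @param ortho_tol Tolerance on orthogonality of the 3x3 block.
#' @return A list with `R` (radians, in `[0, pi]`) and `axis` (degrees in
#'   `[0, 180)`, `NA` when undefined).
#' @export
retardance_params <- function(M_ret, axis_tol = 1e-6, ortho_tol = 1e-6) {
  check_finite(M_ret, "M_ret")
  m <- M_ret[2:4, 2:4]
  if (max(abs(m %*% t(m) - diag(3))) > ortho_tol) {
    stop_invalid("`M_ret` 3x3 block is not orthogonal within tolerance")
  }
  R <- acos(min(1, max(-1, sum(diag(M_ret)) / 2 - 1)))
  if (R < axis_tol) return(list(R = R, axis = NA_real_))
  sR <- sin(R)
  if (sR < 1e-9) {
    # half-wave limit: axis from the doubled-doubled-angle elements;
    # orientation is only determined modulo 90 degrees here
    axis <- axial_mod(atan2(m[1, 2], m[1, 1]) / (4 * DEG2RAD))
  } else {
    a1 <- (m[2, 3] - m[3, 2]) / (2 * sR)
    a2 <- (m[3, 1] - m[1, 3]) / (2 * sR)
    axis <- axial_mod(0.5 * atan2(a2, a1) / DEG2RAD)
  }
  list(R = R, axis = axis)
}

#' Diattenuation magnitude and axis of a Mueller matrix
#'
#' `D = sqrt(m01^2 + m02^2 + m03^2) / m00`; the linear transmission axis is
#' `0.5 * atan2(m02, m01)` mapped to `[0, 180)`.
#'
#' @param M A 4x4 Mueller matrix with `m00 > 0`.
#' @param axis_tol Diattenuation below which the axis is reported `NA`.
#' @return A list with `D` (dimensionless) and `axis` (degrees, `NA` when
#'   undefined).
#' @export
diattenuation_params <- function(M, axis_tol = 1e-6) {
  check_finite(M, "M")
  if (M[1, 1] <= 0) stop_invalid("`M` must have m00 > 0")
  D <- sqrt(sum(M[1, 2:4]^2)) / M[1, 1]
  if (D < axis_tol) return(list(D = D, axis = NA_real_))
  list(D = D, axis = axial_mod(0.5 * atan2(M[1, 3], M[1, 2]) / DEG2RAD))
}

#' Depolarization power of a depolarizer factor
#'
#' `Delta = 1 - |tr(M_depol) - 1| / 3`, ranging from 0 (non-depolarizing)
#' to 1 (ideal depolarizer).
#'
#' @param M_depol A depolarizer Mueller matrix (m00 = 1).
#' @return Depolarization power in `[0, 1]`.
#' @export
depolarization_power <- function(M_depol) {
  check_finite(M_depol, "M_depol")
  min(1, max(0, 1 - abs(sum(diag(M_depol)) - 1) / 3))
}

#' Construct a per-wavelength set of polarization-property maps
#'
#' @param retardance,retardance_angle,diattenuation,diattenuation_angle,depolarization
#'   Numeric matrices of identical dimension.  Angles are degrees on
#'   `[0, 180)` (NA = undefined); retardance is radians.
#' @param wavelength Wavelength in nm.
#' @param validity Logical matrix; invalid pixels are excluded from all
#'   statistics.
#' @param corrected Logical: has phase unwrapping been applied?
#' @return An object of class `polarization_maps`.
#' @export
polarization_maps <- function(retardance, retardance_angle, diattenuation,
                              diattenuation_angle, depolarization,
                              wavelength, validity, corrected = FALSE) {
  d <- dim(retardance)
  for (m in list(retardance_angle, diattenuation, diattenuation_angle,
                 depolarization, validity)) {
    if (!identical(dim(m), d)) stop_invalid("all maps must share one shape")
  }
  structure(list(retardance = retardance, retardance_angle = retardance_angle,
                 diattenuation = diattenuation,
                 diattenuation_angle = diattenuation_angle,
                 depolarization = depolarization,
                 wavelength = wavelength, validity = validity,
                 corrected = corrected),
            class = "polarization_maps")
}

#' @export
print.polarization_maps <- function(x, ...) {
  cat(sprintf("<polarization_maps> %d x %d px at %g nm (%d valid, %s)\n",
              nrow(x$retardance), ncol(x$retardance), x$wavelength,
              sum(x$validity),
              if (isTRUE(x$corrected)) "unwrap-corrected" else "uncorrected"))
  invisible(x)
}

#' Decompose a Mueller image stack into polarization maps
#'
#' Applies the Lu-Chipman decomposition pixel by pixel at every wavelength.
#' Pixels where the decomposition fails (singular or grossly non-physical
#' matrices) are marked invalid in the output and never silently filled; a
#' per-wavelength failure count is recorded in the `"n_failed"` attribute.
#'
#' @param stack A `mueller_stack`.
#' @param axis_tol Retardance / diattenuation magnitude below which the
#'   corresponding angle is reported `NA`.
#' @return A list of `polarization_maps`, one per wavelength, with an
#'   `n_failed` attribute (integer per wavelength).
#' @export
decompose_stack <- function(stack, axis_tol = 1e-6) {
  stopifnot(inherits(stack, "mueller_stack"))
  d <- stack_dim(stack)
  if (any(d == 0)) stop_invalid("`stack` must be non-empty")
  out <- vector("list", d[3])
  n_failed <- integer(d[3])
  for (k in seq_len(d[3])) {
    ret <- ang <- dia <- dang <- dep <- matrix(NA_real_, d[1], d[2])
    val <- matrix(FALSE, d[1], d[2])
    for (rr in seq_len(d[1])) {
      for (cc in seq_len(d[2])) {
        if (!stack$validity[rr, cc, k]) next
        M <- matrix(stack$planes[rr, cc, , k], 4, 4, byrow = TRUE)
        dec <- tryCatch(lu_chipman_decompose(M), error = function(e) NULL)
        if (is.null(dec) || dec$residual > 1e-6) {
          n_failed[k] <- n_failed[k] + 1L
          next
        }
        rp <- tryCatch(
          retardance_params(dec$M_ret, axis_tol = axis_tol, ortho_tol = 1e-3),
          error = function(e) NULL)
        dp <- tryCatch(diattenuation_params(M, axis_tol = axis_tol),
                       error = function(e) NULL)
        if (is.null(rp) || is.null(dp)) {
          n_failed[k] <- n_failed[k] + 1L
          next
        }
        ret[rr, cc] <- rp$R
        ang[rr, cc] <- rp$axis
        dia[rr, cc] <- dp$D
        dang[rr, cc] <- dp$axis
        dep[rr, cc] <- depolarization_power(dec$M_depol)
        val[rr, cc] <- TRUE
      }
    }
    out[[k]] <- polarization_maps(ret, ang, dia, dang, dep,
                                  stack$wavelengths[k], val)
  }
  attr(out, "n_failed") <- n_failed
  out
}
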