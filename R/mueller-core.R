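# Mueller-matrix algebra: elementary polarization elements and frame rotation.
#
# A Mueller matrix is represented as a plain 4x4 numeric matrix, row-major in
# the usual polarimetric sense: row = output Stokes component, column = input
# Stokes component.  Constructors here emit unit-transmittance (m00 = 1)
# elements, except the ideal-polarizer limit of the diattenuator, which uses
# the conventional 0.5 scale (Tmax = 1, Tmin = 0).  Scene-level intensity
# scaling is the simulator's job, not the constructors'.

#' 4x4 identity Mueller matrix
#' @return A 4x4 identity matrix.
#' @export
mueller_identity <- function() diag(4)

#' Stokes rotation matrix
#'
#' Rotation of the polarization reference frame by `phi` degrees
#' (counterclockwise positive).  Acts on the (S1, S2) linear components in
#' doubled-angle space; S0 and S3 are untouched.
#'
#' @param phi Rotation angle in degrees.
#' @return A 4x4 rotation Mueller matrix.
#' @export
stokes_rotation <- function(phi) {
  check_finite(phi, "phi")
  c2 <- cos(2 * phi * DEG2RAD)
  s2 <- sin(2 * phi * DEG2RAD)
  matrix(c(1,  0,   0,  0,
           0,  c2, -s2, 0,
           0,  s2,  c2, 0,
           0,  0,   0,  1), 4, 4, byrow = TRUE)
}

#' Rotate a polarization element
#'
#' Expresses an element with its axis rotated by `phi` degrees via the
#' conjugation `R(phi) %*% M %*% R(-phi)`.  The total transmittance `m00`
#' is unchanged.
#'
#' @param M A 4x4 Mueller matrix.
#' @param phi Rotation angle in degrees (counterclockwise positive).
#' @return The rotated 4x4 Mueller matrix.
#' @export
rotate_element <- function(M, phi) {
  check_finite(M, "M")
  check_finite(phi, "phi")
  stokes_rotation(phi) %*% M %*% stokes_rotation(-phi)
}

#' Linear retarder Mueller matrix
#'
#' Constructs a pure linear retarder with retardance `delta` (radians) and
#' fast axis at `axis` degrees.  The lower-right 3x3 block is a proper
#' rotation (orthogonal, determinant +1).
#'
#' @param delta Retardance in radians (any finite value; the matrix is
#'   2*pi-periodic in `delta`).
#' @param axis Fast-axis orientation in degrees (reduced modulo 180).
#' @return A 4x4 Mueller matrix.
#' @export
#' @examples
#' make_linear_retarder(pi, 0)   # half-wave plate: diag(1, 1, -1, -1)
make_linear_retarder <- function(delta, axis = 0) {
  check_finite(delta, "delta")
  check_finite(axis, "axis")
  cd <- cos(delta)
  sd <- sin(delta)
  M0 <- matrix(c(1, 0, 0,   0,
                 0, 1, 0,   0,
                 0, 0, cd,  sd,
                 0, 0, -sd, cd), 4, 4, byrow = TRUE)
  rotate_element(M0, axial_mod(axis))
}

#' Linear diattenuator Mueller matrix
#'
#' Constructs a pure linear diattenuator with diattenuation magnitude `d`
#' and transmission axis at `axis` degrees.  The matrix is symmetric.  For
#' `d < 1` the element has unit transmittance (m00 = 1); the ideal polarizer
#' `d = 1` uses the conventional 0.5 scale (Tmax = 1, Tmin = 0), so a
#' horizontal polarizer has m00 = m01 = m10 = m11 = 0.5.
#'
#' @param d Diattenuation magnitude in `[0, 1]`.
#' @param axis Transmission-axis orientation in degrees.
#' @return A 4x4 Mueller matrix.
#' @export
make_linear_diattenuator <- function(d, axis = 0) {
  check_range(d, 0, 1, "d")
  check_finite(axis, "axis")
  k <- sqrt(1 - d^2)
  M0 <- matrix(c(1, d, 0, 0,
                 d, 1, 0, 0,
                 0, 0, k, 0,
                 0, 0, 0, k), 4, 4, byrow = TRUE)
  if (d == 1) M0 <- 0.5 * M0
  rotate_element(M0, axial_mod(axis))
}

#' Diagonal depolarizer Mueller matrix
#'
#' Constructs the diagonal depolarizer `diag(1, a, b, c)`, attenuating the
#' three polarized Stokes components independently.
#'
#' @param a,b,c Retained polarization fractions in `[0, 1]` for the S1, S2
#'   and S3 components.
#' @return A 4x4 Mueller matrix.
#' @export
make_depolarizer <- function(a, b = a, c = a) {
  check_range(a, 0, 1, "a")
  check_range(b, 0, 1, "b")
  check_range(c, 0, 1, "c")
  diag(c(1, a, b, c))
}

#' Test physical passivity of a Mueller matrix (element bound)
#'
#' Checks the necessary condition `|mij| <= m00` with `m00 >= 0`.
#'
#' @param M A 4x4 Mueller matrix.
#' @param tol Numerical slack on the comparisons.
#' @return Logical scalar.
#' @export
is_passive_mueller <- function(M, tol = 1e-12) {
  is.matrix(M) && all(dim(M) == c(4, 4)) && all(is.finite(M)) &&
    M[1, 1] >= -tol && all(abs(M) <= M[1, 1] + tol)
}
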