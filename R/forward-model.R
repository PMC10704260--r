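# Tilted-uniaxial-crystal forward model for the retardance of birefringent
# fibers.  A fiber is modeled as a uniaxial medium whose optic axis lies in
# the imaging plane when untilted; inclining the fiber out of plane by
# theta_i reduces the effective extraordinary index seen by the light, hence
# the measured retardance:
#
#   n_e(theta_i) = nO * nE / sqrt(nE^2 sin^2(theta_i) + nO^2 cos^2(theta_i))
#   delta        = (2 pi L / lambda) * |n_e(theta_i) - nO|
#
# The instrument is sensitive only to the magnitude of the retardance, so
# delta is reported as an absolute value; the path length L is treated as
# independent of inclination and wavelength.

#' Construct a uniaxial medium
#'
#' @param nO Ordinary refractive index (> 0).
#' @param nE Extraordinary refractive index (> 0).  Negative birefringence
#'   (`nE < nO`) is the white-matter / polystyrene-fiber case.
#' @param L Path length through the medium in micrometers (> 0).
#' @param delta_n_scale Optional named numeric vector of per-wavelength
#'   multiplicative factors on the birefringence (a dispersion table; names
#'   are wavelengths in nm).  Wavelengths not listed use factor 1.
#' @return An object of class `uniaxial_medium`.
#' @export
#' @examples
#' uniaxial_medium(nO = 1.59, nE = 1.57, L = 10)
uniaxial_medium <- function(nO, nE, L, delta_n_scale = NULL) {
  check_range(nO, 1e-12, Inf, "nO")
  check_range(nE, 1e-12, Inf, "nE")
  check_range(L, 1e-12, Inf, "L")
  if (!is.null(delta_n_scale)) {
    check_finite(delta_n_scale, "delta_n_scale")
    if (is.null(names(delta_n_scale))) {
      stop_invalid("`delta_n_scale` must be named by wavelength (nm)")
    }
  }
  structure(list(nO = nO, nE = nE, L = L, delta_n_scale = delta_n_scale),
            class = "uniaxial_medium")
}

#' Effective extraordinary index under tilt
#'
#' @param medium A `uniaxial_medium`.
#' @param theta_i Inclination (tilt of the optic axis out of the imaging
#'   plane) in degrees, in `[0, 90]`.  Vectorized.
#' @return Effective extraordinary refractive index; equals `nE` at 0 degrees
#'   and `nO` at 90 degrees.
#' @export
effective_index <- function(medium, theta_i) {
  stopifnot(inherits(medium, "uniaxial_medium"))
  check_range(theta_i, 0, 90, "theta_i")
  th <- theta_i * DEG2RAD
  medium$nO * medium$nE /
    sqrt(medium$nE^2 * sin(th)^2 + medium$nO^2 * cos(th)^2)
}

dispersion_factor <- function(medium, wavelength) {
  tab <- medium$delta_n_scale
  if (is.null(tab)) return(rep(1, length(wavelength)))
  f <- tab[as.character(wavelength)]
  f[is.na(f)] <- 1
  unname(f)
}

#' Retardance of an inclined uniaxial medium
#'
#' `delta = (2 pi L / lambda) * |n_e(theta_i) - nO|`, optionally scaled by
#' the medium's per-wavelength dispersion factor.  Magnitude only: the
#' modeled instrument does not sense the sign of the retardance.
#'
#' @param medium A `uniaxial_medium`.
#' @param theta_i Inclination in degrees, in `[0, 90]`.  Vectorized (with
#'   scalar `wavelength`, or equal length).
#' @param wavelength Imaging wavelength in nm (> 0).
#' @return Retardance in radians (>= 0); exactly 0 at 90 degrees tilt.
#' @export
tilted_retardance <- function(medium, theta_i, wavelength) {
  stopifnot(inherits(medium, "uniaxial_medium"))
  check_finite(wavelength, "wavelength")
  if (any(wavelength <= 0)) stop_invalid("`wavelength` must be positive")
  ne_eff <- effective_index(medium, theta_i)
  lambda_um <- wavelength / 1000  # nm -> um, matching L in um
  2 * pi * medium$L / lambda_um * abs(ne_eff - medium$nO) *
    dispersion_factor(medium, wavelength)
}

#' Tabulate retardance-versus-inclination curves
#'
#' Evaluates the forward model on a grid of inclinations for each requested
#' wavelength, for plotting or export.
#'
#' @param medium A `uniaxial_medium`.
#' @param wavelengths Wavelengths in nm.
#' @param theta_grid Inclination grid in degrees (default 0..90 by 1).
#' @param file Optional path; when given, the table is written as
#'   tab-separated text with a unit-bearing header.
#' @return A data.frame with columns `theta_deg`, `wavelength_nm`,
#'   `retardance_rad` (invisibly when `file` is given).
#' @export
retardance_curve_table <- function(medium, wavelengths = pli_wavelengths(),
                                   theta_grid = seq(0, 90, by = 1),
                                   file = NULL) {
  tab <- do.call(rbind, lapply(wavelengths, function(wl) {
    data.frame(theta_deg = theta_grid, wavelength_nm = wl,
               retardance_rad = tilted_retardance(medium, theta_grid, wl))
  }))
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste0("# retardance (radians) vs inclination (degrees); ",
                      "wavelengths in nm"), con)
    utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
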