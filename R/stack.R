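# MuellerImageStack container: per-pixel 4x4 Mueller matrices on a raster
# grid, one plane group per imaging wavelength, plus a per-pixel validity
# mask.  Invalid pixels carry NA in all 16 element planes and are excluded
# from every downstream statistic.

#' Default imaging wavelengths (nm)
#'
#' The five-wavelength set of the backscattering polarimeter this package
#' models: 405, 442, 473, 532 and 632 nm.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
pli_wavelengths <- function() c(405, 442, 473, 532, 632)

#' Construct a Mueller-matrix image stack
#'
#' @param planes Numeric array `[height, width, 16, n_wavelengths]`.  The 16
#'   element planes are ordered row-major: m00, m01, ..., m33.
#' @param wavelengths Strictly ascending, unique, positive wavelengths (nm),
#'   one per plane group.
#' @param pixel_pitch Physical pixel pitch in micrometers.
#' @param validity Logical array `[height, width, n_wavelengths]`; defaults
#'   to all pixels whose 16 elements are finite.
#' @param metadata Optional named list carried along (seed, creation log,
#'   corrected-flag and the like).
#' @return An object of class `mueller_stack`.
#' @export
mueller_stack <- function(planes, wavelengths, pixel_pitch = 10,
                          validity = NULL, metadata = list()) {
  if (!is.array(planes) || length(dim(planes)) != 4 || dim(planes)[3] != 16) {
    stop_invalid("`planes` must be a [H, W, 16, n_wavelengths] array")
  }
  nw <- dim(planes)[4]
  if (length(wavelengths) != nw) {
    stop_invalid("length(wavelengths) must match the number of plane groups")
  }
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0) ||
      any(diff(wavelengths) <= 0)) {
    stop_invalid("`wavelengths` must be positive, unique and strictly ascending")
  }
  check_range(pixel_pitch, 1e-9, Inf, "pixel_pitch")
  if (is.null(validity)) {
    validity <- apply(planes, c(1, 2, 4), function(v) all(is.finite(v)))
  }
  if (!identical(dim(validity), dim(planes)[c(1, 2, 4)])) {
    stop_invalid("`validity` must be a [H, W, n_wavelengths] logical array")
  }
  # invalid pixels carry the NA sentinel in every element plane
  for (k in seq_len(nw)) {
    bad <- !validity[, , k]
    if (any(bad)) {
      for (e in 1:16) {
        pl <- planes[, , e, k]
        pl[bad] <- NA_real_
        planes[, , e, k] <- pl
      }
    }
  }
  structure(list(planes = planes, wavelengths = as.numeric(wavelengths),
                 pixel_pitch = pixel_pitch,
                 validity = array(as.logical(validity), dim(planes)[c(1, 2, 4)]),
                 metadata = metadata),
            class = "mueller_stack")
}

#' Stack dimensions
#' @param stack A `mueller_stack`.
#' @return Integer vector `c(height, width, n_wavelengths)`.
#' @export
stack_dim <- function(stack) {
  stopifnot(inherits(stack, "mueller_stack"))
  dim(stack$planes)[c(1, 2, 4)]
}

#' Extract the 4x4 Mueller matrix at one pixel
#'
#' @param stack A `mueller_stack`.
#' @param row,col Pixel indices (1-based).
#' @param wavelength_index Index into `stack$wavelengths`.
#' @return A 4x4 matrix, or `NULL` for an invalid pixel.
#' @export
stack_pixel <- function(stack, row, col, wavelength_index = 1) {
  if (!stack$validity[row, col, wavelength_index]) return(NULL)
  matrix(stack$planes[row, col, , wavelength_index], 4, 4, byrow = TRUE)
}

#' @export
print.mueller_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf("<mueller_stack> %d x %d px, %d wavelength(s): %s nm, pitch %g um\n",
              d[1], d[2], d[3], paste(x$wavelengths, collapse = ", "),
              x$pixel_pitch))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$validity), length(x$validity)))
  invisible(x)
}

# internal: build an empty planes array
empty_planes <- function(h, w, nw) array(NA_real_, c(h, w, 16, nw))
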