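# ROI analyses of polarization maps: masked Gaussian smoothing, axial
# angular histograms ("radial plots"), path profiles with linear fits, and
# the rotation-series registration and fitting.
#
# All angle statistics respect axial (180-degree) periodicity: angle maps
# are smoothed and interpolated in doubled-angle vector space
# (cos 2*theta, sin 2*theta), and angle means are circular means of axial
# data.

#' Construct an ROI mask
#'
#' @param flags Logical matrix marking member pixels.
#' @param label Free-text label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(flags, label = "") {
  if (!is.logical(flags) || !is.matrix(flags)) {
    stop_invalid("`flags` must be a logical matrix")
  }
  structure(list(flags = flags, label = label), class = "roi_mask")
}

roi_flags <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$flags else mask
}

# ---- masked Gaussian smoothing ------------------------------------------

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# zero-padded separable convolution by shift-and-add
conv_sep <- function(x, k) {
  r <- (length(k) - 1) / 2
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {             # rows
    d <- j - r - 1
    src <- seq_len(h) + d
    ok <- src >= 1 & src <= h
    out[ok, ] <- out[ok, ] + k[j] * x[src[ok], , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (j in seq_along(k)) {             # columns
    d <- j - r - 1
    src <- seq_len(w) + d
    ok <- src >= 1 & src <= w
    out2[, ok] <- out2[, ok] + k[j] * out[, src[ok], drop = FALSE]
  }
  out2
}

masked_gauss <- function(map, weight, k) {
  m0 <- map
  m0[weight == 0 | is.na(m0)] <- 0
  num <- conv_sep(m0 * weight, k)
  den <- conv_sep(weight, k)
  out <- num / den
  out[den < 1e-12] <- NA_real_
  out
}

#' Gaussian smoothing of polarization maps
#'
#' Scalar maps (retardance, diattenuation, depolarization) are filtered with
#' a normalized masked 2-D Gaussian: invalid pixels contribute nothing and
#' the kernel weight is renormalized over the valid support, so valid-region
#' structure is denoised without bleeding in sentinel values.  Angle maps
#' are filtered in doubled-angle vector space to respect their 180-degree
#' periodicity.
#'
#' @param maps A `polarization_maps` object.
#' @param sigma Gaussian standard deviation in pixels (default 10, the
#'   pipeline's standard smoothing); `sigma = 0` is the identity.
#' @return A smoothed `polarization_maps` object (validity unchanged).
#' @export
smooth_maps <- function(maps, sigma = 10) {
  stopifnot(inherits(maps, "polarization_maps"))
  check_finite(sigma, "sigma")
  if (sigma < 0) stop_invalid("`sigma` must be >= 0")
  if (sigma == 0) return(maps)
  k <- gaussian_kernel_1d(sigma)
  v <- maps$validity * 1

  sm_scalar <- function(map) {
    w <- v * !is.na(map)
    out <- masked_gauss(map, w, k)
    out[!maps$validity] <- NA_real_
    out
  }
  sm_angle <- function(ang) {
    w <- v * !is.na(ang)
    a <- ang * DEG2RAD
    cs <- masked_gauss(cos(2 * a), w, k)
    sn <- masked_gauss(sin(2 * a), w, k)
    out <- axial_mod(0.5 * atan2(sn, cs) / DEG2RAD)
    out[is.na(cs) | is.na(sn) | !maps$validity] <- NA_real_
    out
  }
  polarization_maps(sm_scalar(maps$retardance), sm_angle(maps$retardance_angle),
                    sm_scalar(maps$diattenuation),
                    sm_angle(maps$diattenuation_angle),
                    sm_scalar(maps$depolarization),
                    maps$wavelength, maps$validity, maps$corrected)
}

# ---- angular histograms --------------------------------------------------

#' Axial angular distribution over an ROI
#'
#' Histogram of an angle map over `[0, 180)`, optionally weighted (e.g. by
#' retardance), normalized so the maximum height is 1 -- the package
#' counterpart of a radial plot whose largest spoke marks the most frequent
#' orientation.
#'
#' @param angle_map Matrix of angles in degrees on `[0, 180)`; `NA` entries
#'   are excluded.
#' @param mask An `roi_mask` or logical matrix selecting the ROI.
#' @param weights_map Optional non-negative weight matrix (same shape).
#' @param n_bins Number of equal bins over `[0, 180)` (default 36, i.e.
#'   5-degree bins); at least 4.
#' @return An object of class `angular_histogram` with fields `bin_edges`
#'   (degrees), `heights` (max 1), `dominant_angle` (degrees; center of the
#'   modal bin, ties resolved by the circular mean of tied bin centers) and
#'   `n_pixels`.
#' @export
angular_distribution <- function(angle_map, mask, weights_map = NULL,
                                 n_bins = 36) {
  if (n_bins < 4) stop_invalid("`n_bins` must be at least 4")
  f <- roi_flags(mask)
  if (!identical(dim(f), dim(angle_map))) {
    stop_invalid("mask shape does not match the angle map")
  }
  sel <- f & !is.na(angle_map)
  if (!any(f)) {
    stop(structure(class = c("muellerpli_empty_roi", "error", "condition"),
                   list(message = "empty ROI mask", call = NULL)))
  }
  a <- axial_mod(angle_map[sel])
  w <- if (is.null(weights_map)) rep(1, length(a)) else weights_map[sel]
  keep <- !is.na(w) & w >= 0
  a <- a[keep]; w <- w[keep]
  width <- 180 / n_bins
  edges <- seq(0, 180, by = width)
  heights <- numeric(n_bins)
  if (length(a)) {
    idx <- pmin(floor(a / width) + 1L, n_bins)
    for (i in seq_along(a)) heights[idx[i]] <- heights[idx[i]] + w[i]
  }
  mx <- max(heights)
  dominant <- NA_real_
  if (mx > 0) {
    centers <- edges[-length(edges)] + width / 2
    tied <- which(heights >= mx - 1e-12 * mx)
    dominant <- if (length(tied) == 1) centers[tied] else axial_mean(centers[tied])
    heights <- heights / mx
  }
  structure(list(bin_edges = edges, heights = heights,
                 dominant_angle = dominant, n_pixels = sum(sel)),
            class = "angular_histogram")
}

#' @export
print.angular_histogram <- function(x, ...) {
  cat(sprintf("<angular_histogram> %d bins, %d px, dominant %.1f deg\n",
              length(x$heights), x$n_pixels, x$dominant_angle))
  invisible(x)
}

# ---- path profiles -------------------------------------------------------

#' Mean-value profile along a polyline path
#'
#' Resamples the polyline at 1-pixel arc-length stations and, at each
#' station, averages the valid map pixels within `transverse_width / 2` of
#' the path along the local normal.
#'
#' @param map Numeric matrix (a scalar polarization map; `NA` = invalid).
#' @param path Matrix with columns (x = column, y = row) in pixel
#'   coordinates, at least 2 vertices, inside the image bounds.
#' @param transverse_width Averaging width in micrometers.
#' @param pixel_pitch Pixel pitch in micrometers (converts widths and
#'   station positions to physical units).
#' @return An object of class `path_profile` with `stations` (arc length in
#'   micrometers), `values` (mean per station; `NA` where every transverse
#'   pixel was invalid) and `transverse_width`.
#' @export
profile_along_path <- function(map, path, transverse_width, pixel_pitch = 10) {
  if (!is.matrix(path) || ncol(path) != 2 || nrow(path) < 2) {
    stop_invalid("`path` must be a matrix of >= 2 (x, y) vertices")
  }
  h <- nrow(map); w <- ncol(map)
  if (any(path[, 1] < 1 | path[, 1] > w | path[, 2] < 1 | path[, 2] > h)) {
    stop(structure(class = c("muellerpli_out_of_bounds", "error", "condition"),
                   list(message = "path exits image bounds", call = NULL)))
  }
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) == 0) stop_invalid("`path` has zero length")
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s_px <- seq(0, total, by = 1)
  hw_px <- (transverse_width / pixel_pitch) / 2
  offs <- if (hw_px < 0.5) 0 else seq(-floor(hw_px), floor(hw_px), by = 1)

  values <- numeric(length(s_px))
  for (i in seq_along(s_px)) {
    s <- s_px[i]
    j <- max(1, min(nrow(seg), findInterval(s, cum, rightmost.closed = TRUE)))
    t <- if (seg_len[j] > 0) (s - cum[j]) / seg_len[j] else 0
    p <- path[j, ] + t * seg[j, ]
    dir <- seg[j, ] / seg_len[j]
    nrm <- c(-dir[2], dir[1])
    px <- round(p[1] + offs * nrm[1])
    py <- round(p[2] + offs * nrm[2])
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    vals <- map[cbind(py[ok], px[ok])]
    vals <- vals[!is.na(vals)]
    values[i] <- if (length(vals)) mean(vals) else NA_real_
  }
  structure(list(stations = s_px * pixel_pitch, values = values,
                 transverse_width = transverse_width),
            class = "path_profile")
}

#' Ordinary least-squares line through a path profile
#'
#' @param profile A `path_profile`.
#' @return A list with `slope` (map units per micrometer), `intercept`,
#'   `r_squared`, `residual_sd` and `n` (valid stations used).
#' @export
linear_fit_profile <- function(profile) {
  stopifnot(inherits(profile, "path_profile"))
  ok <- !is.na(profile$values)
  if (sum(ok) < 2) stop(insufficient_data("need >= 2 valid stations"))
  x <- profile$stations[ok]; y <- profile$values[ok]
  fit <- stats::lm(y ~ x)
  # noise-free inputs fit exactly; the perfect-fit warning is expected
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (stats::var(y) > 0) sm$r.squared else NA_real_,
       residual_sd = sm$sigma, n = sum(ok))
}

#' Export an angular histogram or path profile as delimited text
#'
#' Writes tab-separated values with a comment header naming units and the
#' shared angle convention.
#'
#' @param x An `angular_histogram` or `path_profile`.
#' @param file Destination path.
#' @return Invisibly, the path.
#' @export
export_analysis_table <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (inherits(x, "angular_histogram")) {
    writeLines(c(paste0("# angular histogram; ", mueller_convention()),
                 sprintf("# n_pixels = %d; dominant_angle_deg = %.9g",
                         x$n_pixels, x$dominant_angle)), con)
    tab <- data.frame(bin_start_deg = x$bin_edges[-length(x$bin_edges)],
                      bin_end_deg = x$bin_edges[-1],
                      height = x$heights)
  } else if (inherits(x, "path_profile")) {
    writeLines(c("# path profile; stations in um along the path",
                 sprintf("# transverse_width_um = %.9g", x$transverse_width)),
               con)
    tab <- data.frame(station_um = x$stations, value = x$values)
  } else {
    stop_invalid("`x` must be an angular_histogram or path_profile")
  }
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

# ---- rotation registration and series fits ------------------------------

# inverse-mapped bilinear rotation; angle counterclockwise, y-axis up
rotate_field <- function(get_val, h, w, angle_deg, center) {
  th <- angle_deg * DEG2RAD
  cg <- expand.grid(r = seq_len(h), c = seq_len(w))
  dx <- cg$c - center[2]
  dy <- -(cg$r - center[1])
  # inverse rotation of output coords to find the source location
  dxs <- cos(th) * dx + sin(th) * dy
  dys <- -sin(th) * dx + cos(th) * dy
  cs <- center[2] + dxs
  rs <- center[1] - dys
  get_val(rs, cs)
}

bilinear <- function(map, valid, rs, cs) {
  h <- nrow(map); w <- ncol(map)
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  out <- rep(NA_real_, length(rs))
  inb <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
  # exact grid hits at the borders
  edge <- !inb & rs >= 1 & rs <= h & cs >= 1 & cs <= w &
    abs(rs - round(rs)) < 1e-9 & abs(cs - round(cs)) < 1e-9
  if (any(inb)) {
    i00 <- cbind(r0[inb], c0[inb]); i01 <- cbind(r0[inb], c0[inb] + 1)
    i10 <- cbind(r0[inb] + 1, c0[inb]); i11 <- cbind(r0[inb] + 1, c0[inb] + 1)
    ok <- valid[i00] & valid[i01] & valid[i10] & valid[i11]
    vv <- (1 - fr[inb]) * (1 - fc[inb]) * map[i00] +
      (1 - fr[inb]) * fc[inb] * map[i01] +
      fr[inb] * (1 - fc[inb]) * map[i10] +
      fr[inb] * fc[inb] * map[i11]
    vv[!ok] <- NA_real_
    out[inb] <- vv
  }
  if (any(edge)) {
    ie <- cbind(round(rs[edge]), round(cs[edge]))
    ve <- map[ie]
    ve[!valid[ie]] <- NA_real_
    out[edge] <- ve
  }
  out
}

#' Co-register a rotated acquisition back to the unrotated frame
#'
#' Undoes a known stage rotation: map content is rigidly rotated by
#' `-stage_angle` about `center` with bilinear interpolation, and angle-map
#' values are additionally shifted by `-stage_angle` (mod 180) so that
#' orientations are expressed in the common frame.  Regions mapped from
#' outside the original frame are marked invalid.
#'
#' @param maps A `polarization_maps` object acquired at stage angle
#'   `stage_angle`.
#' @param stage_angle Stage rotation in degrees (counterclockwise positive).
#' @param center Rotation center as `c(row, col)`; default image center.
#' @return The registered `polarization_maps`.
#' @export
register_rotation <- function(maps, stage_angle, center = NULL) {
  stopifnot(inherits(maps, "polarization_maps"))
  check_finite(stage_angle, "stage_angle")
  if (stage_angle %% 360 == 0) return(maps)
  h <- nrow(maps$retardance); w <- ncol(maps$retardance)
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)

  rot_scalar <- function(map) {
    v <- rotate_field(function(rs, cs) bilinear(map, maps$validity, rs, cs),
                      h, w, -stage_angle, center)
    matrix(v, h, w)
  }
  rot_angle <- function(ang) {
    va <- maps$validity & !is.na(ang)
    a <- ang * DEG2RAD
    csm <- cos(2 * a); snm <- sin(2 * a)
    csm[!va] <- NA; snm[!va] <- NA
    cs <- rotate_field(function(rs, cc) bilinear(csm, va, rs, cc),
                       h, w, -stage_angle, center)
    sn <- rotate_field(function(rs, cc) bilinear(snm, va, rs, cc),
                       h, w, -stage_angle, center)
    out <- axial_mod(0.5 * atan2(sn, cs) / DEG2RAD - stage_angle)
    out[is.na(cs) | is.na(sn)] <- NA_real_
    matrix(out, h, w)
  }
  ret <- rot_scalar(maps$retardance)
  validity <- !is.na(rot_scalar(maps$validity * 1))
  polarization_maps(ret, rot_angle(maps$retardance_angle),
                    rot_scalar(maps$diattenuation),
                    rot_angle(maps$diattenuation_angle),
                    rot_scalar(maps$depolarization),
                    maps$wavelength, validity, maps$corrected)
}

#' Construct a rotation series record
#'
#' Per-ROI mean retardance and circular-mean retardance angle at each stage
#' orientation.
#'
#' @param orientations Unique stage angles in degrees.
#' @param retardance_mean,angle_mean Numeric matrices `[n_roi, n_orient]`.
#' @param roi_labels Optional ROI labels.
#' @return An object of class `rotation_series`.
#' @export
rotation_series <- function(orientations, retardance_mean, angle_mean,
                            roi_labels = NULL) {
  if (anyDuplicated(orientations)) stop_invalid("orientations must be unique")
  retardance_mean <- rbind(retardance_mean)
  angle_mean <- rbind(angle_mean)
  if (ncol(retardance_mean) != length(orientations) ||
      !identical(dim(retardance_mean), dim(angle_mean))) {
    stop_invalid("means must be [n_roi, n_orientations] matrices")
  }
  if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(nrow(retardance_mean)))
  structure(list(orientations = orientations,
                 retardance_mean = retardance_mean, angle_mean = angle_mean,
                 roi_labels = roi_labels),
            class = "rotation_series")
}

#' Summarize registered rotation acquisitions into a rotation series
#'
#' @param maps_list List of `polarization_maps`, one per orientation,
#'   already registered to a common frame.
#' @param orientations Stage angles in degrees matching `maps_list`.
#' @param rois List of `roi_mask` / logical matrices.
#' @return A `rotation_series`.
#' @export
rotation_series_from_maps <- function(maps_list, orientations, rois) {
  stopifnot(length(maps_list) == length(orientations))
  nr <- length(rois)
  rmean <- amean <- matrix(NA_real_, nr, length(orientations))
  for (j in seq_along(maps_list)) {
    m <- maps_list[[j]]
    for (i in seq_len(nr)) {
      sel <- roi_flags(rois[[i]]) & m$validity
      rmean[i, j] <- mean(m$retardance[sel], na.rm = TRUE)
      amean[i, j] <- axial_mean(m$retardance_angle[sel])
    }
  }
  rotation_series(orientations, rmean, amean,
                  roi_labels = vapply(rois, function(r) {
                    if (inherits(r, "roi_mask")) r$label else ""
                  }, character(1)))
}

#' Fit orientation trends in a rotation series
#'
#' Per ROI, fits (i) the 180-degree-periodic sinusoid
#' `a * cos(2 * (phi - phi0)) + c` to the mean retardance versus stage
#' orientation (requires >= 4 orientations; refused otherwise), and (ii) a
#' straight line to the axially unwrapped mean retardance angle versus
#' orientation, whose slope is expected near 1 when the recovered axis
#' tracks the stage.
#'
#' @param series A `rotation_series`.
#' @return A list (one element per ROI) of lists with components `sinusoid`
#'   (`amplitude`, `phase_deg`, `offset`, `r_squared`; or `NULL` when
#'   refused) and `angle_line` (`slope`, `intercept`, `r_squared`).
#' @export
rotation_series_analysis <- function(series) {
  stopifnot(inherits(series, "rotation_series"))
  phi <- series$orientations
  if (length(phi) < 2) stop(insufficient_data("need >= 2 orientations"))
  ord <- order(phi)
  phi <- phi[ord]
  lapply(seq_len(nrow(series$retardance_mean)), function(i) {
    r <- series$retardance_mean[i, ord]
    a <- series$angle_mean[i, ord]

    sinus <- NULL
    okr <- !is.na(r)
    if (sum(okr) >= 4) {
      cc <- cos(2 * phi[okr] * DEG2RAD); ss <- sin(2 * phi[okr] * DEG2RAD)
      fit <- stats::lm(r[okr] ~ cc + ss)
      A <- stats::coef(fit)[["cc"]]; B <- stats::coef(fit)[["ss"]]
      sinus <- list(amplitude = sqrt(A^2 + B^2),
                    phase_deg = axial_mod(0.5 * atan2(B, A) / DEG2RAD),
                    offset = stats::coef(fit)[[1]],
                    r_squared = suppressWarnings(summary(fit))$r.squared)
    }

    oka <- which(!is.na(a))
    angle_line <- NULL
    if (length(oka) >= 2) {
      au <- numeric(length(oka))
      au[1] <- a[oka[1]]
      for (j in seq_along(oka)[-1]) {
        step <- phi[oka[j]] - phi[oka[j - 1]]
        au[j] <- au[j - 1] + step + axial_diff(a[oka[j]], au[j - 1] + step)
      }
      fit <- stats::lm(au ~ phi[oka])
      sm <- suppressWarnings(summary(fit))
      angle_line <- list(slope = unname(stats::coef(fit)[2]),
                         intercept = unname(stats::coef(fit)[1]),
                         r_squared = sm$r.squared)
    }
    list(sinusoid = sinus, angle_line = angle_line)
  })
}
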