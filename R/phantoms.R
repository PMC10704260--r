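# Synthetic fiber-phantom generator: renders scenes of birefringent fibers
# (crossing, inclined, cylinder-wrapped, in-plane-looping, rotated) to
# multi-wavelength Mueller-matrix image stacks with full per-pixel ground
# truth.
#
# Physics per pixel: the background is a pure diagonal depolarizer (a dark
# foil has no anisotropy); a fiber pixel is that depolarizer composed with a
# linear retarder whose retardance follows the tilted-uniaxial forward model
# and whose fast axis is the local fiber tangent for positively birefringent
# material, or the tangent + 90 degrees for negatively birefringent material
# (the axis-perpendicular-to-fiber signature of white matter and polystyrene
# fibers).  Where fibers overlap, either the top fiber alone provides the
# signal ("top": resolved-fiber behavior) or the single-fiber matrices are
# averaged element-wise ("average": unresolved bulk-tissue behavior).

#' Construct a fiber specification
#'
#' @param centerline Matrix with columns (x = column, y = row) in pixel
#'   coordinates describing the fiber centerline polyline.
#' @param diameter Fiber diameter in micrometers.
#' @param medium A `uniaxial_medium` describing the fiber material.
#' @param birefringence_sign `"negative"` (retardance axis perpendicular to
#'   the fiber; white matter / polystyrene case) or `"positive"` (axis along
#'   the fiber; PVC synthetic-hair case).
#' @param inclination Out-of-plane inclination profile in degrees: a single
#'   number (constant), or a function of arc length in micrometers returning
#'   degrees in `[0, 90]` (see [cylinder_wrap_profile()]).
#' @param z_order Integer stacking rank; larger is on top.
#' @param diattenuation Optional list `list(d =, axis = "tangent")` or
#'   `list(d =, axis = <degrees>)` adding a linear diattenuator to the
#'   fiber's response.
#' @return An object of class `fiber_spec`.
#' @export
fiber_spec <- function(centerline, diameter, medium,
                       birefringence_sign = c("negative", "positive"),
                       inclination = 0, z_order = 1L, diattenuation = NULL) {
  birefringence_sign <- match.arg(birefringence_sign)
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2 || nrow(centerline) < 2) {
    stop_invalid("`centerline` must be a matrix of >= 2 (x, y) vertices")
  }
  check_range(diameter, 1e-9, Inf, "diameter")
  stopifnot(inherits(medium, "uniaxial_medium"))
  if (is.numeric(inclination)) check_range(inclination, 0, 90, "inclination")
  structure(list(centerline = centerline, diameter = diameter,
                 medium = medium, birefringence_sign = birefringence_sign,
                 inclination = inclination, z_order = as.integer(z_order),
                 diattenuation = diattenuation),
            class = "fiber_spec")
}

#' Cylinder-wrap inclination profile
#'
#' A fiber laid over a cylinder of radius `radius` acquires an inclination
#' `asin(s / radius)` at arc position `s` past the tangency point, clipped
#' to `[0, 90]` degrees.
#'
#' @param radius Cylinder radius in micrometers.
#' @param s0 Arc position (micrometers) of the tangency point (inclination 0
#'   before it).
#' @return A function mapping arc length (um) to inclination (degrees).
#' @export
cylinder_wrap_profile <- function(radius, s0 = 0) {
  check_range(radius, 1e-9, Inf, "radius")
  function(s) {
    u <- pmax(0, pmin(1, (s - s0) / radius))
    asin(u) / DEG2RAD
  }
}

#' Construct a phantom scene
#'
#' @param fibers List of `fiber_spec`.
#' @param size Image size in pixels, `c(height, width)` (a scalar means
#'   square).
#' @param pixel_pitch Pixel pitch in micrometers (default 10, the modeled
#'   instrument's resolution scale).
#' @param wavelengths Imaging wavelengths in nm (default the instrument's
#'   five-wavelength set).
#' @param background Depolarizer parameters `c(a, b, c)` of the dark foil
#'   background.
#' @param overlap_mode `"top"` or `"average"`; must be set whenever any two
#'   fiber footprints intersect.
#' @param noise Per-wavelength Gaussian sigma on Mueller elements (relative
#'   to each pixel's m00); scalar is recycled.
#' @param seed Integer seed recorded with the scene and used for noise.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(fibers, size = 64, pixel_pitch = 10,
                          wavelengths = pli_wavelengths(),
                          background = c(0.2, 0.2, 0.2),
                          overlap_mode = c("top", "average"),
                          noise = 0, seed = 1L) {
  overlap_mode <- match.arg(overlap_mode)
  if (length(size) == 1) size <- c(size, size)
  z <- vapply(fibers, function(f) f$z_order, integer(1))
  if (anyDuplicated(z)) stop_invalid("fiber z_order values must be unique")
  noise <- rep_len(noise, length(wavelengths))
  if (any(noise < 0)) stop_invalid("noise sigmas must be >= 0")
  structure(list(fibers = fibers, size = size, pixel_pitch = pixel_pitch,
                 wavelengths = wavelengths, background = background,
                 overlap_mode = overlap_mode, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

#' Rasterize one fiber's geometry
#'
#' Dilates the centerline to the fiber diameter and derives, per footprint
#' pixel, the local tangent orientation and the inclination interpolated by
#' arc length.
#'
#' @param spec A `fiber_spec`.
#' @param size Image size `c(height, width)` in pixels.
#' @param pitch Pixel pitch in micrometers.
#' @return A list with `footprint` (logical matrix), `tangent` (degrees,
#'   `NA` outside), `inclination` (degrees, `NA` outside) and `arc`
#'   (micrometers, `NA` outside).
#' @export
render_fiber_geometry <- function(spec, size, pitch) {
  if (length(size) == 1) size <- c(size, size)
  h <- size[1]; w <- size[2]
  radius_px <- spec$diameter / (2 * pitch)
  cl <- spec$centerline
  if (any(cl[, 1] < 1 + radius_px | cl[, 1] > w - radius_px |
          cl[, 2] < 1 + radius_px | cl[, 2] > h - radius_px)) {
    stop(structure(class = c("muellerpli_out_of_bounds", "error", "condition"),
                   list(message = "dilated centerline exits image bounds",
                        call = NULL)))
  }
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  best_d2 <- matrix(Inf, h, w)
  tangent <- arc <- matrix(NA_real_, h, w)
  seg <- diff(cl)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  for (j in seq_len(nrow(seg))) {
    if (seg_len[j] == 0) next
    dx <- X - cl[j, 1]; dy <- Y - cl[j, 2]
    t <- (dx * seg[j, 1] + dy * seg[j, 2]) / seg_len[j]^2
    t <- pmin(1, pmax(0, t))
    px <- dx - t * seg[j, 1]
    py <- dy - t * seg[j, 2]
    d2 <- px^2 + py^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      # tangent in the axial convention (y axis up, CCW positive)
      tangent[upd] <- axial_mod(atan2(-seg[j, 2], seg[j, 1]) / DEG2RAD)
      arc[upd] <- (cum[j] + t[upd] * seg_len[j]) * pitch
    }
  }
  footprint <- best_d2 <= radius_px^2
  tangent[!footprint] <- NA_real_
  arc[!footprint] <- NA_real_
  incl <- matrix(NA_real_, h, w)
  if (is.function(spec$inclination)) {
    incl[footprint] <- pmin(90, pmax(0, spec$inclination(arc[footprint])))
  } else {
    incl[footprint] <- spec$inclination
  }
  list(footprint = footprint, tangent = tangent, inclination = incl,
       arc = arc)
}

fiber_axis <- function(tangent, sign) {
  if (sign == "negative") axial_mod(tangent + 90) else tangent
}

#' Render a phantom scene to a Mueller image stack with ground truth
#'
#' @param scene A `phantom_scene`.
#' @return A list with `stack` (a `mueller_stack`) and `truth` (class
#'   `ground_truth`: per-pixel `fiber_id` (0 = background), `axis`
#'   (convention-adjusted retardance axis, degrees), `inclination`
#'   (degrees), `retardance` (radians, `[H, W, n_wavelengths]`),
#'   `diattenuation` and `overlap` (logical: pixels covered by more than one
#'   fiber)).  In overlap regions the recorded truth is the
#'   top fiber's; noise (if any) is added after the truth is recorded.
#' @export
scene_to_mueller <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (length(scene$wavelengths) == 0) stop_invalid("wavelengths must be non-empty")
  h <- scene$size[1]; w <- scene$size[2]
  nw <- length(scene$wavelengths)
  bg <- make_depolarizer(scene$background[1], scene$background[2],
                         scene$background[3])
  bg_vec <- as.vector(t(bg))

  planes <- array(rep(bg_vec, each = h * w), c(h, w, 16, nw))
  fiber_id <- matrix(0L, h, w)
  axis_map <- incl_map <- matrix(NA_real_, h, w)
  diatt_map <- matrix(0, h, w)
  ret_arr <- array(0, c(h, w, nw))

  geoms <- lapply(scene$fibers, render_fiber_geometry, scene$size,
                  scene$pixel_pitch)
  cover <- matrix(0L, h, w)
  for (g in geoms) cover <- cover + g$footprint
  if (any(cover > 1) && is.null(scene$overlap_mode)) {
    stop_invalid("fiber footprints overlap but overlap_mode is unset")
  }
  zord <- vapply(scene$fibers, function(f) f$z_order, integer(1))

  # per-fiber per-pixel matrices, combined by overlap mode
  acc <- array(0, c(h, w, 16, nw))       # running sum (average mode)
  top_z <- matrix(-Inf, h, w)
  for (fi in order(zord)) {
    f <- scene$fibers[[fi]]
    g <- geoms[[fi]]
    idx <- which(g$footprint)
    if (!length(idx)) next
    ax <- fiber_axis(g$tangent[idx], f$birefringence_sign)
    newtop <- zord[fi] > top_z[idx]
    # ground truth follows the top fiber
    gt <- idx[newtop]
    fiber_id[gt] <- fi
    axis_map[gt] <- ax[newtop]
    incl_map[gt] <- g$inclination[idx][newtop]
    diatt_map[gt] <- if (is.null(f$diattenuation)) 0 else f$diattenuation$d
    for (k in seq_len(nw)) {
      delta <- tilted_retardance(f$medium, g$inclination[idx],
                                 scene$wavelengths[k])
      ret_arr[gt + (k - 1) * h * w] <- delta[newtop]
      for (ii in seq_along(idx)) {
        M <- bg %*% make_linear_retarder(delta[ii], ax[ii])
        if (!is.null(f$diattenuation)) {
          dax <- if (identical(f$diattenuation$axis, "tangent")) {
            g$tangent[idx[ii]]
          } else {
            f$diattenuation$axis
          }
          M <- M %*% make_linear_diattenuator(f$diattenuation$d, dax)
        }
        Mv <- as.vector(t(M))
        p <- idx[ii]
        if (scene$overlap_mode == "top") {
          if (newtop[ii]) {
            planes[p + ((1:16) - 1) * h * w + (k - 1) * 16 * h * w] <- Mv
          }
        } else {
          acc[p + ((1:16) - 1) * h * w + (k - 1) * 16 * h * w] <-
            acc[p + ((1:16) - 1) * h * w + (k - 1) * 16 * h * w] + Mv
        }
      }
    }
    top_z[idx] <- pmax(top_z[idx], zord[fi])
  }
  if (scene$overlap_mode == "average") {
    idx <- which(cover > 0)
    for (k in seq_len(nw)) {
      for (e in 1:16) {
        off <- (e - 1) * h * w + (k - 1) * 16 * h * w
        planes[idx + off] <- acc[idx + off] / cover[idx]
      }
    }
  }

  truth <- structure(list(fiber_id = fiber_id, axis = axis_map,
                          inclination = incl_map, retardance = ret_arr,
                          diattenuation = diatt_map, overlap = cover > 1L),
                     class = "ground_truth")
  stack <- mueller_stack(planes, scene$wavelengths, scene$pixel_pitch,
                         metadata = list(seed = scene$seed,
                                         overlap_mode = scene$overlap_mode,
                                         angle_convention = mueller_convention()))
  if (any(scene$noise > 0)) {
    stack <- add_noise(stack, scene$noise, scene$seed)
  }
  list(stack = stack, truth = truth)
}

#' The package's angle convention string
#'
#' @return A single string documenting the shared axial-angle convention.
#' @export
mueller_convention <- function() {
  paste("axial degrees on [0,180); 0 deg horizontal pointing right;",
        "counterclockwise positive; retardance angle = FAST axis")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  code
}

#' Add wavelength-dependent Gaussian noise to a Mueller stack
#'
#' Adds i.i.d. zero-mean Gaussian perturbations to every Mueller element,
#' scaled by the pixel's m00.  Deterministic under a fixed seed.  Noisy
#' matrices violating the passivity bound `|mij| <= m00` are flagged in the
#' output metadata (`nonphysical`), never repaired.
#'
#' @param stack A `mueller_stack`.
#' @param sigma_per_wavelength Noise sigma per wavelength (>= 0), length
#'   matching `stack$wavelengths`.
#' @param seed Integer seed.
#' @return A noisy `mueller_stack`.
#' @export
add_noise <- function(stack, sigma_per_wavelength, seed = 1L) {
  stopifnot(inherits(stack, "mueller_stack"))
  d <- stack_dim(stack)
  if (length(sigma_per_wavelength) != d[3]) {
    stop_invalid("sigma list length must match the number of wavelengths")
  }
  if (any(sigma_per_wavelength < 0)) stop_invalid("sigmas must be >= 0")
  if (all(sigma_per_wavelength == 0)) return(stack)
  planes <- stack$planes
  nonphys <- array(FALSE, d)
  with_seed(seed, {
    for (k in seq_len(d[3])) {
      if (sigma_per_wavelength[k] == 0) next
      m00 <- planes[, , 1, k]
      eps <- array(stats::rnorm(d[1] * d[2] * 16, sd = sigma_per_wavelength[k]),
                   c(d[1], d[2], 16))
      for (e in 1:16) {
        planes[, , e, k] <- planes[, , e, k] + eps[, , e] * m00
      }
      mx <- apply(abs(planes[, , , k]), c(1, 2), max)
      nonphys[, , k] <- is.finite(mx) & mx > planes[, , 1, k]
    }
  })
  md <- stack$metadata
  md$nonphysical <- nonphys
  md$noise_sigma <- sigma_per_wavelength
  md$seed <- as.integer(seed)
  mueller_stack(planes, stack$wavelengths, stack$pixel_pitch,
                validity = stack$validity, metadata = md)
}

# line through the image center with direction theta (deg, axial convention)
center_line <- function(size, theta, margin) {
  h <- size[1]; w <- size[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  dx <- cos(theta * DEG2RAD); dy <- -sin(theta * DEG2RAD)  # row axis down
  tmax <- Inf
  if (abs(dx) > 1e-12) tmax <- min(tmax, (min(cx - 1, w - cx) - margin) / abs(dx))
  if (abs(dy) > 1e-12) tmax <- min(tmax, (min(cy - 1, h - cy) - margin) / abs(dy))
  rbind(c(cx - tmax * dx, cy - tmax * dy), c(cx + tmax * dx, cy + tmax * dy))
}

#' Default phantom fiber material
#'
#' A polystyrene-like negatively birefringent medium (nO = 1.59, nE = 1.57,
#' birefringence -0.02) with a 10 um effective path length, the generator's
#' default fiber material.
#'
#' @return A `uniaxial_medium`.
#' @export
default_medium <- function() uniaxial_medium(nO = 1.59, nE = 1.57, L = 10)

#' Ready-made phantom scenes mirroring the experimental series
#'
#' * `crossing`: two straight fibers crossing at the image center at
#'   `params$crossing_angle` (default 60 deg), z-ordered.
#' * `inclined_series`: one scene per inclination in
#'   `params$inclinations` (default 0, 15, ..., 90 deg), each with
#'   `params$n_fibers` (default 3) parallel horizontal fibers at that
#'   constant inclination.
#' * `cylinder_wrap`: one horizontal fiber whose inclination ramps as the
#'   arc wraps a cylinder of `params$radius` micrometers.
#' * `inplane_loop`: one fiber following a circular loop in the imaging
#'   plane.
#' * `rotation_series`: the same straight fiber rotated about the image
#'   center over `params$stage_angles` (default 15 orientations, 0 to 168
#'   deg by 12), one scene per orientation.
#'
#' Common params: `size`, `pixel_pitch`, `wavelengths`, `diameter` (um),
#' `medium`, `birefringence_sign`, `background`, `noise`, `seed`,
#' `overlap_mode`, `direction` (base fiber orientation, degrees).
#'
#' @param name One of `"crossing"`, `"inclined_series"`, `"cylinder_wrap"`,
#'   `"inplane_loop"`, `"rotation_series"`.
#' @param params Named list of overrides (see above).
#' @return A `phantom_scene`, or a list of scenes for the series presets
#'   (with attribute `"series_values"` naming each scene's inclination or
#'   stage angle).
#' @export
preset_phantom <- function(name, params = list()) {
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  size <- p("size", 64); if (length(size) == 1) size <- c(size, size)
  pitch <- p("pixel_pitch", 10)
  wl <- p("wavelengths", pli_wavelengths())
  diameter <- p("diameter", 60)
  medium <- p("medium", default_medium())
  sign <- p("birefringence_sign", "negative")
  background <- p("background", c(0.2, 0.2, 0.2))
  noise <- p("noise", 0)
  seed <- p("seed", 1L)
  direction <- p("direction", 0)
  margin <- diameter / (2 * pitch) + 1

  scene1 <- function(fibers, overlap = p("overlap_mode", "top"), sd = seed) {
    phantom_scene(fibers, size = size, pixel_pitch = pitch, wavelengths = wl,
                  background = background, overlap_mode = overlap,
                  noise = noise, seed = sd)
  }
  straight <- function(theta, incl = 0, z = 1L) {
    fiber_spec(center_line(size, theta, margin), diameter, medium,
               birefringence_sign = sign, inclination = incl, z_order = z)
  }

  switch(name,
    crossing = {
      ca <- p("crossing_angle", 60)
      scene1(list(straight(direction - ca / 2, z = 1L),
                  straight(direction + ca / 2, z = 2L)))
    },
    inclined_series = {
      incls <- p("inclinations", seq(0, 90, by = 15))
      nf <- p("n_fibers", 3)
      rows <- round(seq(0.25, 0.75, length.out = nf) * size[1])
      scenes <- lapply(incls, function(th_i) {
        fibers <- lapply(seq_len(nf), function(i) {
          xr <- c(1 + margin, size[2] - margin)
          fiber_spec(rbind(c(xr[1], rows[i]), c(xr[2], rows[i])), diameter,
                     medium, birefringence_sign = sign, inclination = th_i,
                     z_order = i)
        })
        scene1(fibers)
      })
      structure(scenes, series_values = incls)
    },
    cylinder_wrap = {
      radius <- p("radius", 1000)
      xr <- c(1 + margin, size[2] - margin)
      yc <- (size[1] + 1) / 2
      fib <- fiber_spec(rbind(c(xr[1], yc), c(xr[2], yc)), diameter, medium,
                        birefringence_sign = sign,
                        inclination = cylinder_wrap_profile(radius),
                        z_order = 1L)
      scene1(list(fib))
    },
    inplane_loop = {
      rad_px <- p("loop_radius_px", min(size) / 2 - margin - 2)
      th <- seq(0, 2 * pi, length.out = p("n_vertices", 181))
      cl <- cbind((size[2] + 1) / 2 + rad_px * cos(th),
                  (size[1] + 1) / 2 + rad_px * sin(th))
      scene1(list(fiber_spec(cl, diameter, medium, birefringence_sign = sign,
                             z_order = 1L)))
    },
    rotation_series = {
      angles <- p("stage_angles", seq(0, by = 12, length.out = 15))
      incl <- p("inclination", 0)
      scenes <- lapply(angles, function(a) {
        scene1(list(straight(direction + a, incl = incl)), sd = seed)
      })
      structure(scenes, series_values = angles)
    },
    stop_invalid("unknown preset name: ", name)
  )
}
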