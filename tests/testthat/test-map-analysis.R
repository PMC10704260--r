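# ROI analyses: masked smoothing, angular histograms, path profiles, linear
# fits, rotation registration and rotation-series fitting.

make_maps <- function(ret, ang = NULL, validity = NULL, wavelength = 532) {
  h <- nrow(ret); w <- ncol(ret)
  if (is.null(ang)) ang <- matrix(45, h, w)
  if (is.null(validity)) validity <- matrix(TRUE, h, w)
  polarization_maps(ret, ang, ret * 0.1, ang, ret * 0, wavelength, validity)
}

test_that("smoothing leaves constant maps unchanged and sigma = 0 is identity", {
  m <- make_maps(matrix(1.3, 20, 20), matrix(77, 20, 20))
  s <- smooth_maps(m, sigma = 3)
  expect_equal(s$retardance, m$retardance, tolerance = 1e-12)
  expect_equal(s$retardance_angle, m$retardance_angle, tolerance = 1e-9)
  expect_identical(smooth_maps(m, 0), m)
  expect_error(smooth_maps(m, -1), class = "muellerpli_invalid_argument")
})

test_that("a unit impulse smooths to the discrete Gaussian kernel", {
  n <- 31
  ret <- matrix(0, n, n); ret[16, 16] <- 1
  s <- smooth_maps(make_maps(ret), sigma = 2)
  k1 <- dnorm(seq(-6, 6), sd = 2); k1 <- k1 / sum(k1)
  expected <- outer(k1, k1)
  expect_equal(s$retardance[10:22, 10:22], expected, tolerance = 1e-10)
})

test_that("smoothing conserves the total of an interior-supported map", {
  # support far enough from the border that no kernel mass is lost there
  set.seed(2)
  ret <- matrix(0, 40, 40)
  ret[17:23, 17:23] <- runif(49)
  s <- smooth_maps(make_maps(ret), sigma = 2)
  expect_equal(sum(s$retardance), sum(ret), tolerance = 1e-6)
})

test_that("invalid pixels are excluded by the normalized masked convolution", {
  ret <- matrix(1, 15, 15)
  ret[8, 8] <- 1000               # value hidden behind an invalid pixel
  v <- matrix(TRUE, 15, 15); v[8, 8] <- FALSE
  s <- smooth_maps(make_maps(ret, validity = v), sigma = 2)
  expect_lt(max(abs(s$retardance[v] - 1)), 1e-9)
  expect_true(is.na(s$retardance[8, 8]))
})

test_that("angle maps are smoothed axially (no 0/180 seam artifacts)", {
  # angles hovering around the 0/180 seam must average near the seam,
  # not near 90
  ang <- matrix(c(178, 2), 10, 10)
  s <- smooth_maps(make_maps(matrix(1, 10, 10), ang), sigma = 2)
  expect_true(all(pmin(s$retardance_angle, 180 - s$retardance_angle) < 3))
})

test_that("angular distribution normalizes, finds the dominant bin, handles ties", {
  a45 <- matrix(45.1, 8, 8)
  h <- angular_distribution(a45, matrix(TRUE, 8, 8))
  expect_equal(max(h$heights), 1)
  expect_equal(sum(h$heights > 0), 1)
  expect_equal(h$dominant_angle, 47.5)   # center of the 5-deg bin [45, 50)
  expect_equal(h$n_pixels, 64)

  # two-value tie: dominant is the circular mean of the tied bin centers
  tie <- matrix(c(30.1, 120.1), 10, 10)
  ht <- angular_distribution(tie, matrix(TRUE, 10, 10))
  expect_equal(sum(abs(ht$heights - 1) < 1e-12), 2)
  expect_equal(ht$dominant_angle, axial_mean(c(32.5, 122.5)))

  # weighting moves the dominant bin
  wmap <- matrix(c(1, 10), 10, 10)
  hw <- angular_distribution(tie, matrix(TRUE, 10, 10), weights_map = wmap)
  expect_equal(hw$dominant_angle, 122.5)

  expect_error(angular_distribution(a45, matrix(FALSE, 8, 8)),
               class = "muellerpli_empty_roi")
  expect_error(angular_distribution(a45, matrix(TRUE, 8, 8), n_bins = 3),
               class = "muellerpli_invalid_argument")
})

test_that("angular distribution is rotation equivariant up to bin width", {
  set.seed(9)
  base <- matrix(runif(400, 0, 180), 20, 20)
  roi <- matrix(TRUE, 20, 20)
  h0 <- angular_distribution(base, roi, n_bins = 36)
  for (phi in c(15, 50, 120)) {
    h1 <- angular_distribution(axial_mod(base + phi), roi, n_bins = 36)
    expect_lte(axial_dist(h1$dominant_angle, h0$dominant_angle + phi), 5)
  }
})

test_that("path profiles average transverse pixels and respect bounds", {
  m <- matrix(2.5, 30, 30)
  path <- rbind(c(3, 15), c(28, 15))
  p <- profile_along_path(m, path, transverse_width = 50, pixel_pitch = 10)
  expect_true(all(p$values == 2.5))
  expect_equal(p$stations, seq(0, 250, by = 10))

  # map linear in x sampled along a horizontal path: matching slope per um
  lin <- matrix(rep(seq_len(30), each = 30), 30, 30)  # value = column index
  pl <- profile_along_path(lin, path, transverse_width = 30, pixel_pitch = 10)
  fit <- linear_fit_profile(pl)
  expect_equal(fit$slope, 1 / 10, tolerance = 1e-10)  # 1 unit per 10 um
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)

  expect_error(profile_along_path(m, rbind(c(3, 15)), 50, 10),
               class = "muellerpli_invalid_argument")
  expect_error(profile_along_path(m, rbind(c(3, 15), c(40, 15)), 50, 10),
               class = "muellerpli_out_of_bounds")
})

test_that("profile stations with only invalid pixels carry the NA sentinel", {
  m <- matrix(1, 20, 20)
  m[, 10] <- NA
  p <- profile_along_path(m, rbind(c(2, 10), c(19, 10)), 0, pixel_pitch = 1)
  expect_true(any(is.na(p$values)))
  expect_true(any(!is.na(p$values)))
})

test_that("linear fit recovers a noisy slope within 3 standard errors", {
  set.seed(4)
  x <- seq(0, 500, by = 10)
  sigma <- 0.05; slope_true <- -2e-3; icpt <- 2.0
  ok <- TRUE
  for (i in 1:20) {
    y <- icpt + slope_true * x + rnorm(length(x), sd = sigma)
    prof <- structure(list(stations = x, values = y, transverse_width = 0),
                      class = "path_profile")
    fit <- linear_fit_profile(prof)
    se <- sigma / sqrt(sum((x - mean(x))^2))
    ok <- ok && abs(fit$slope - slope_true) < 3 * se
  }
  expect_true(ok)
  # degenerate inputs
  flat <- structure(list(stations = x, values = rep(1, length(x)),
                         transverse_width = 0), class = "path_profile")
  expect_equal(linear_fit_profile(flat)$slope, 0, tolerance = 1e-12)
  two <- structure(list(stations = c(0, 1), values = c(NA, 1),
                        transverse_width = 0), class = "path_profile")
  expect_error(linear_fit_profile(two), class = "muellerpli_insufficient_data")
})

test_that("rotation registration undoes a known stage rotation", {
  sc <- preset_phantom("rotation_series",
                       list(size = 33, wavelengths = 532, stage_angles = c(0, 90),
                            direction = 0))
  m0 <- decompose_stack(scene_to_mueller(sc[[1]])$stack)[[1]]
  m90 <- decompose_stack(scene_to_mueller(sc[[2]])$stack)[[1]]
  reg <- register_rotation(m90, 90)
  # a 90-degree registration is an exact grid permutation away from the
  # border: compare the central region to the unrotated acquisition
  ctr <- 9:25
  expect_equal(reg$retardance[ctr, ctr], m0$retardance[ctr, ctr],
               tolerance = 1e-9)
  da <- axial_dist(reg$retardance_angle[ctr, ctr], m0$retardance_angle[ctr, ctr])
  expect_lt(max(da, na.rm = TRUE), 1e-6)
  # identity case
  expect_identical(register_rotation(m0, 0), m0)
})

test_that("registered angle values are shifted by minus the stage angle", {
  ang <- matrix(30, 21, 21)
  m <- make_maps(matrix(1, 21, 21), ang)
  reg <- register_rotation(m, 40)
  inner <- reg$retardance_angle[8:14, 8:14]
  expect_equal(unique(as.numeric(round(inner, 6))), 170)  # (30 - 40) mod 180
})

test_that("rotation-series fits find a flat sinusoid and unit angle slope", {
  phis <- seq(0, 168, by = 12)
  # constant retardance, angle tracking the stage exactly
  rs <- rotation_series(phis, matrix(1.5, 1, length(phis)),
                        matrix(axial_mod(20 + phis), 1))
  an <- rotation_series_analysis(rs)[[1]]
  expect_lt(an$sinusoid$amplitude, 1e-12)
  expect_equal(an$angle_line$slope, 1, tolerance = 1e-10)
  expect_equal(an$angle_line$r_squared, 1, tolerance = 1e-10)

  # a genuine sinusoid is recovered
  r <- 0.4 * cos(2 * (phis - 30) * pi / 180) + 2
  rs2 <- rotation_series(phis, rbind(r), matrix(axial_mod(phis), 1))
  an2 <- rotation_series_analysis(rs2)[[1]]
  expect_equal(an2$sinusoid$amplitude, 0.4, tolerance = 1e-8)
  expect_equal(an2$sinusoid$phase_deg, 30, tolerance = 1e-6)
  expect_equal(an2$sinusoid$offset, 2, tolerance = 1e-8)

  # two orientations: sinusoid refused, line still returned
  rs3 <- rotation_series(c(0, 20), rbind(c(1, 1)), rbind(c(10, 30)))
  an3 <- rotation_series_analysis(rs3)[[1]]
  expect_null(an3$sinusoid)
  expect_equal(an3$angle_line$slope, 1, tolerance = 1e-10)
  expect_error(rotation_series(c(0, 0), rbind(c(1, 1)), rbind(c(1, 1))),
               class = "muellerpli_invalid_argument")
})
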