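# Synthetic phantom generator: rasterized geometry, Mueller rendering,
# overlap modes, presets, noise determinism, and end-to-end recovery.

test_that("straight-fiber rasterization has the analytic tangent and footprint", {
  med <- uniaxial_medium(1.59, 1.57, 10)
  spec <- fiber_spec(rbind(c(6, 16), c(27, 16)), diameter = 60, medium = med)
  g <- render_fiber_geometry(spec, size = 32, pitch = 10)
  expect_true(all(g$tangent[g$footprint] == 0))
  expect_true(all(is.na(g$tangent[!g$footprint])))
  # footprint is the 3-px-radius dilation of the centerline row
  expect_true(all(g$footprint[14:18, 10]))
  expect_false(any(g$footprint[c(12, 20), 10]))
  # out-of-bounds centerline is refused
  expect_error(render_fiber_geometry(
    fiber_spec(rbind(c(1, 16), c(31, 16)), 60, med), 32, 10),
    class = "muellerpli_out_of_bounds")
})

test_that("loop centerline tangents match the analytic circle tangent", {
  sc <- preset_phantom("inplane_loop",
                       list(size = 64, wavelengths = 532, diameter = 30))
  g <- render_fiber_geometry(sc$fibers[[1]], sc$size, sc$pixel_pitch)
  ctr <- c((64 + 1) / 2, (64 + 1) / 2)
  idx <- which(g$footprint, arr.ind = TRUE)
  # analytic tangent of a circle at the pixel's polar angle (y axis up)
  pol <- atan2(-(idx[, 1] - ctr[1]), idx[, 2] - ctr[2])
  expected <- axial_mod(pol / (pi / 180) + 90)
  err <- axial_dist(g$tangent[g$footprint], expected)
  expect_lt(stats::quantile(err, 0.98), 1)   # away from raster corners
  expect_lt(max(err), 3)
})

test_that("cylinder-wrap inclination follows arcsin(arc / radius)", {
  prof <- cylinder_wrap_profile(radius = 500)
  s <- c(0, 100, 250, 500, 800)
  expect_equal(prof(s), c(0, asin(0.2), asin(0.5), pi / 2, pi / 2) * 180 / pi)
  sc <- preset_phantom("cylinder_wrap",
                       list(size = 32, wavelengths = 532, radius = 400))
  g <- render_fiber_geometry(sc$fibers[[1]], sc$size, sc$pixel_pitch)
  ok <- g$footprint
  expect_equal(g$inclination[ok],
               pmin(90, asin(pmin(1, g$arc[ok] / 400)) * 180 / pi),
               tolerance = 1e-12)
})

test_that("empty scenes render to the pure background depolarizer", {
  sc <- phantom_scene(list(), size = 8, wavelengths = c(442, 532),
                      background = c(0.3, 0.4, 0.5))
  r <- scene_to_mueller(sc)
  expect_true(all(r$truth$fiber_id == 0))
  M <- stack_pixel(r$stack, 4, 4, 2)
  expect_equal(M, make_depolarizer(0.3, 0.4, 0.5))
})

test_that("birefringence sign sets the rendered axis convention", {
  # negative: axis perpendicular to the fiber; positive: parallel
  for (cfg in list(c("negative", 90), c("positive", 0))) {
    sc <- small_fiber_scene(direction = 0, sign = cfg[1])
    r <- scene_to_mueller(sc)
    fib <- r$truth$fiber_id > 0
    expect_true(all(r$truth$axis[fib] == as.numeric(cfg[2])))
    m <- decompose_stack(r$stack)[[1]]
    expect_lt(max(axial_dist(m$retardance_angle[fib], as.numeric(cfg[2]))),
              1e-6)
  }
})

test_that("top overlap mode copies the top fiber's matrices bit for bit", {
  sc <- preset_phantom("crossing", list(size = 32, wavelengths = 532))
  r <- scene_to_mueller(sc)
  ov <- which(r$truth$overlap)
  expect_gt(length(ov), 0)
  expect_true(all(r$truth$fiber_id[ov] == 2))
  # single-fiber reference scene for the top fiber only
  sc1 <- phantom_scene(sc$fibers[2], size = sc$size,
                       pixel_pitch = sc$pixel_pitch, wavelengths = 532,
                       background = sc$background)
  r1 <- scene_to_mueller(sc1)
  for (e in 1:16) {
    expect_identical(r$stack$planes[, , e, 1][ov], r1$stack$planes[, , e, 1][ov])
  }
})

test_that("average overlap mode is the element-wise mean of the fibers", {
  sc <- preset_phantom("crossing", list(size = 32, wavelengths = 532,
                                        overlap_mode = "average"))
  r <- scene_to_mueller(sc)
  ov <- which(r$truth$overlap)
  singles <- lapply(1:2, function(i) {
    scene_to_mueller(phantom_scene(sc$fibers[i], size = sc$size,
                                   pixel_pitch = sc$pixel_pitch,
                                   wavelengths = 532,
                                   background = sc$background))$stack
  })
  for (e in 1:16) {
    avg <- (singles[[1]]$planes[, , e, 1][ov] + singles[[2]]$planes[, , e, 1][ov]) / 2
    expect_equal(r$stack$planes[, , e, 1][ov], avg, tolerance = 1e-12)
  }
})

test_that("inclined-series ground truth retardance is monotone in tilt", {
  scn <- preset_phantom("inclined_series",
                        list(size = 24, wavelengths = 532,
                             inclinations = seq(0, 50, by = 10), n_fibers = 1))
  expect_length(scn, 6)
  means <- vapply(scn, function(s) {
    r <- scene_to_mueller(s)
    mean(r$truth$retardance[, , 1][r$truth$fiber_id > 0])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("rotation-series ground-truth axis tracks the stage angle", {
  angles <- seq(0, by = 12, length.out = 15)
  scn <- preset_phantom("rotation_series",
                        list(size = 24, wavelengths = 532, direction = 10,
                             stage_angles = angles))
  expect_length(scn, 15)
  for (i in c(1, 6, 15)) {
    r <- scene_to_mueller(scn[[i]])
    fib <- r$truth$fiber_id > 0
    # negative birefringence: axis = direction + stage + 90
    expect_lt(max(axial_dist(r$truth$axis[fib], 10 + angles[i] + 90)), 1e-9)
  }
  expect_error(preset_phantom("unknown"), class = "muellerpli_invalid_argument")
})

test_that("diattenuating fibers render a recoverable diattenuation", {
  med <- uniaxial_medium(1.59, 1.57, 10)
  fib <- fiber_spec(rbind(c(8, 16), c(25, 16)), 60, med,
                    birefringence_sign = "positive",
                    diattenuation = list(d = 0.25, axis = "tangent"))
  r <- scene_to_mueller(phantom_scene(list(fib), size = 32, wavelengths = 532))
  m <- decompose_stack(r$stack)[[1]]
  sel <- r$truth$fiber_id > 0
  expect_equal(unique(round(m$diattenuation[sel], 9)), 0.25)
  expect_lt(max(axial_dist(m$diattenuation_angle[sel], 0)), 1e-6)
})

test_that("noise is seed-deterministic, m00-scaled, and zero-sigma is identity", {
  sc <- small_fiber_scene()
  r <- scene_to_mueller(sc)
  expect_identical(add_noise(r$stack, 0), r$stack)
  n1 <- add_noise(r$stack, 0.02, seed = 7)
  n2 <- add_noise(r$stack, 0.02, seed = 7)
  expect_identical(n1$planes, n2$planes)
  n3 <- add_noise(r$stack, 0.02, seed = 8)
  expect_false(identical(n1$planes, n3$planes))
  expect_error(add_noise(r$stack, c(0.1, 0.1)),
               class = "muellerpli_invalid_argument")
})

test_that("noise growing with wavelength drives non-decreasing failure counts", {
  sc <- preset_phantom("rotation_series",
                       list(size = 16, wavelengths = c(405, 532, 632),
                            stage_angles = 0, diameter = 80))[[1]]
  clean <- scene_to_mueller(sc)$stack
  sig <- c(0.01, 0.1, 0.35)
  tot <- c(0, 0, 0)
  for (seed in 1:50) {
    noisy <- add_noise(clean, sig, seed = seed)
    tot <- tot + attr(decompose_stack(noisy), "n_failed")
  }
  expect_true(all(diff(tot) >= 0))
  expect_gt(tot[3], tot[1])
})

test_that("noise-free end-to-end recovery is exact on every preset geometry", {
  presets <- list(
    preset_phantom("crossing", list(size = 32, wavelengths = 532)),
    preset_phantom("cylinder_wrap", list(size = 32, wavelengths = 532,
                                         radius = 400)),
    preset_phantom("inplane_loop", list(size = 48, wavelengths = 532,
                                        diameter = 30)))
  for (sc in presets) {
    r <- scene_to_mueller(sc)
    m <- decompose_stack(r$stack)[[1]]
    fib <- r$truth$fiber_id > 0 & r$truth$retardance[, , 1] > 1e-3 &
      r$truth$retardance[, , 1] < pi - 1e-3
    expect_equal(m$retardance[fib], r$truth$retardance[, , 1][fib],
                 tolerance = 1e-8)
    expect_lt(max(axial_dist(m$retardance_angle[fib], r$truth$axis[fib])), 0.1)
  }
})
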