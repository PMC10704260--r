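# Lu-Chipman decomposition: factor recovery, parameter extraction, the
# wrapping identity, rotation equivariance, and stack-level contracts.

test_that("identity and pure elements decompose to themselves", {
  d <- lu_chipman_decompose(diag(4))
  expect_equal(d$M_depol, diag(4), tolerance = 1e-10)
  expect_equal(d$M_ret, diag(4), tolerance = 1e-10)
  expect_equal(d$M_diatt, diag(4), tolerance = 1e-10)

  M <- make_linear_retarder(1.2, 30)
  d <- lu_chipman_decompose(M)
  expect_equal(d$M_ret, M, tolerance = 1e-10)
  expect_equal(d$M_depol, diag(4), tolerance = 1e-10)
  expect_equal(d$M_diatt, diag(4), tolerance = 1e-10)
})

test_that("forward-composed triples are recovered factor by factor", {
  MD <- make_depolarizer(0.7, 0.7, 0.7)
  MR <- make_linear_retarder(0.8, 10)
  MT <- make_linear_diattenuator(0.3, 50)
  d <- lu_chipman_decompose(MD %*% MR %*% MT)
  expect_equal(d$M_depol, MD, tolerance = 1e-8)
  expect_equal(d$M_ret, MR, tolerance = 1e-8)
  expect_equal(d$M_diatt, MT, tolerance = 1e-8)
  expect_lt(d$residual, 1e-8)
})

test_that("retardance and diattenuation parameters round-trip constructors", {
  rp <- retardance_params(make_linear_retarder(0.8, 10))
  expect_equal(rp$R, 0.8, tolerance = 1e-10)
  expect_equal(rp$axis, 10, tolerance = 1e-10)

  rp0 <- retardance_params(diag(4))
  expect_equal(rp0$R, 0)
  expect_true(is.na(rp0$axis))

  # phase wrap: retardance 4.0 is mirrored around pi, axis flips 90 deg
  rp4 <- retardance_params(lu_chipman_decompose(make_linear_retarder(4, 10))$M_ret)
  expect_equal(rp4$R, 2 * pi - 4, tolerance = 1e-10)
  expect_equal(rp4$axis, 100, tolerance = 1e-8)

  dp <- diattenuation_params(make_linear_diattenuator(0.3, 50))
  expect_equal(dp$D, 0.3, tolerance = 1e-12)
  expect_equal(dp$axis, 50, tolerance = 1e-10)
  expect_true(is.na(diattenuation_params(diag(4))$axis))
  pol <- diattenuation_params(make_linear_diattenuator(1, 0))
  expect_equal(pol$D, 1, tolerance = 1e-12)
  expect_equal(pol$axis, 0, tolerance = 1e-10)
  expect_error(retardance_params(make_linear_diattenuator(0.9, 0)),
               class = "muellerpli_invalid_argument")
  expect_error(diattenuation_params(diag(c(0, 1, 1, 1))),
               class = "muellerpli_invalid_argument")
})

test_that("depolarization power follows the trace formula", {
  expect_equal(depolarization_power(diag(4)), 0)
  expect_equal(depolarization_power(make_depolarizer(0.5, 0.6, 0.7)), 0.4)
})

test_that("wrap identity: recovered params of delta in (pi, 2pi) are mirrored", {
  set.seed(3)
  for (i in 1:50) {
    d <- runif(1, pi + 1e-3, 2 * pi - 1e-3)
    th <- runif(1, 0, 180)
    rp <- retardance_params(
      lu_chipman_decompose(make_linear_retarder(d, th))$M_ret)
    expect_equal(rp$R, 2 * pi - d, tolerance = 1e-8)
    expect_equal(axial_dist(rp$axis, th + 90), 0, tolerance = 1e-6)
  }
})

test_that("decomposition is rotation equivariant", {
  set.seed(5)
  for (i in 1:25) {
    tr <- random_triple()
    M <- tr$depol %*% tr$ret %*% tr$diatt
    phi <- runif(1, 0, 180)
    d0 <- lu_chipman_decompose(M)
    d1 <- lu_chipman_decompose(rotate_element(M, phi))
    r0 <- retardance_params(d0$M_ret); r1 <- retardance_params(d1$M_ret)
    expect_equal(r1$R, r0$R, tolerance = 1e-8)
    expect_equal(axial_dist(r1$axis, r0$axis + phi), 0, tolerance = 1e-6)
    t0 <- diattenuation_params(M); t1 <- diattenuation_params(rotate_element(M, phi))
    expect_equal(t1$D, t0$D, tolerance = 1e-8)
    expect_equal(axial_dist(t1$axis, t0$axis + phi), 0, tolerance = 1e-6)
    expect_equal(depolarization_power(d1$M_depol),
                 depolarization_power(d0$M_depol), tolerance = 1e-8)
  }
})

test_that("grossly non-physical matrices raise a decomposition failure", {
  bad <- diag(4); bad[1, 1] <- 0
  expect_error(lu_chipman_decompose(bad),
               class = "muellerpli_decomposition_failure")
  overpol <- diag(4); overpol[1, 2] <- 1.5
  expect_error(lu_chipman_decompose(overpol),
               class = "muellerpli_decomposition_failure")
})

test_that("decompose_stack maps a synthetic fiber exactly and isolates bad pixels", {
  sc <- small_fiber_scene(direction = 20, sign = "positive")
  r <- scene_to_mueller(sc)
  # corrupt one pixel at all wavelengths
  r$stack$planes[5, 5, , ] <- 0
  maps <- decompose_stack(r$stack)
  m <- maps[[1]]
  expect_false(m$validity[5, 5])
  expect_equal(sum(!m$validity), 1)
  fib <- r$truth$fiber_id > 0
  fib[5, 5] <- FALSE
  expect_equal(m$retardance[fib], r$truth$retardance[, , 1][fib],
               tolerance = 1e-8)
  expect_lt(max(axial_dist(m$retardance_angle[fib], r$truth$axis[fib])), 0.1)
  expect_equal(attr(maps, "n_failed"), 1L)

  # identity stack: zero maps, angles flagged undefined
  pl <- array(rep(as.vector(t(diag(4))), each = 4), c(2, 2, 16, 1))
  ident <- decompose_stack(mueller_stack(pl, 532))[[1]]
  expect_true(all(ident$retardance == 0))
  expect_true(all(is.na(ident$retardance_angle)))
  expect_true(all(ident$diattenuation == 0))
  expect_true(all(ident$depolarization == 0))
})
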