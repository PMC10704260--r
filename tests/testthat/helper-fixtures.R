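# Shared fixtures: random physical compositions and small phantom scenes.

# one random depolarizer * retarder * diattenuator triple
random_triple <- function() {
  list(depol = make_depolarizer(runif(1, 0.1, 1), runif(1, 0.1, 1),
                                runif(1, 0.1, 1)),
       ret = make_linear_retarder(runif(1, 1e-3, pi - 1e-3), runif(1, 0, 180)),
       diatt = make_linear_diattenuator(runif(1, 0, 0.9), runif(1, 0, 180)))
}

# stations of linear-retarder matrices with retardance ramping over `range`
# at a fixed true axis; returns recovered (wrapped) params per station
decomposed_ramp <- function(delta_range, axis_true, n = 100) {
  delta <- seq(delta_range[1], delta_range[2], length.out = n)
  rec <- t(vapply(delta, function(d) {
    dec <- lu_chipman_decompose(make_linear_retarder(d, axis_true))
    rp <- retardance_params(dec$M_ret)
    c(rp$R, rp$axis)
  }, numeric(2)))
  list(delta_true = delta, R = rec[, 1], axis = rec[, 2])
}

# small single-wavelength straight-fiber scene for end-to-end tests
small_fiber_scene <- function(direction = 0, sign = "negative",
                              wavelengths = 532, size = 32, noise = 0,
                              seed = 1L, inclination = 0) {
  preset_phantom("rotation_series",
                 list(size = size, wavelengths = wavelengths,
                      direction = direction, birefringence_sign = sign,
                      stage_angles = 0, noise = noise, seed = seed,
                      inclination = inclination))[[1]]
}
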