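test_that("baseband combination forms I/Q from the differential pairs", {
  fr <- tibble::tibble(b3 = c(0, 1, 2), b4 = c(0, 1, 1),
                       b5 = c(1, 1, 0), b6 = c(0, 1, 3))
  z <- combine_baseband(fr, fs = 2000)$z
  expect_equal(z, c(1 + 0i, 0 + 0i, -3 + 1i))
  # common-mode content cancels for any constant on all four channels
  fr2 <- tibble::tibble(b3 = 7.3, b4 = 7.3, b5 = 7.3, b6 = 7.3)
  expect_equal(combine_baseband(fr2, fs = 10)$z, 0 + 0i)
  bad <- list(b3 = 1:3, b4 = 1:2, b5 = 1:3, b6 = 1:3)
  expect_error(combine_baseband(tibble::tibble(b3 = 1), fs = 1),
               class = "radarheart_invalid_input")
})

test_that("ellipse fit recovers circles and known ellipses", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  f <- fit_ellipse(complex(real = cos(th), imaginary = sin(th)))
  expect_equal(Mod(f$center), 0, tolerance = 1e-9)
  expect_equal(f$a, 1, tolerance = 1e-9)
  expect_equal(f$b, 1, tolerance = 1e-9)

  th <- seq(0.2, 2 * pi, length.out = 40)
  z <- distort_ellipse(complex(real = cos(th), imaginary = sin(th)),
                       center = 0.2 - 0.1i, a = 1.0, b = 0.6, tilt = 0.5)
  f <- fit_ellipse(z)
  expect_equal(Re(f$center), 0.2, tolerance = 1e-6)
  expect_equal(Im(f$center), -0.1, tolerance = 1e-6)
  expect_equal(f$a, 1.0, tolerance = 1e-6)
  expect_equal(f$b, 0.6, tolerance = 1e-6)
  expect_equal(f$tilt, 0.5, tolerance = 1e-6)

  # refit on a well-distributed subset reproduces the parameters
  f2 <- fit_ellipse(z[seq(1, 40, by = 7)])
  expect_equal(f2$a, f$a, tolerance = 1e-6)
  expect_equal(f2$tilt, f$tilt, tolerance = 1e-6)
})

test_that("ellipse fit rejects insufficient or degenerate geometry", {
  expect_error(fit_ellipse(complex(real = 1:4, imaginary = c(0, 1, 0, -1))),
               class = "radarheart_insufficient_data")
  expect_error(fit_ellipse(complex(real = 1:8, imaginary = 2 * (1:8))),
               class = "radarheart_degenerate_geometry")
  expect_error(fit_ellipse(rep(1 + 1i, 10)),
               class = "radarheart_insufficient_data")
})

test_that("compensation inverts the baseband-error distortion", {
  th <- seq(0, 2 * pi, length.out = 50)[-50]
  circ <- complex(real = cos(th), imaginary = sin(th))
  ident <- structure(list(center = 0 + 0i, a = 1, b = 1, tilt = 0),
                     class = "rh_ellipse")
  expect_equal(compensate_iq(circ, ident), circ)

  set.seed(42)
  for (k in 1:10) {
    ctr <- complex(real = runif(1, -2, 2), imaginary = runif(1, -2, 2))
    ax <- sort(runif(2, 0.2, 5))
    tilt <- runif(1, -pi / 2, pi / 2 - 1e-3)
    z <- distort_ellipse(circ, ctr, ax[2], ax[1], tilt)
    f <- fit_ellipse(z)
    expect_lt(max(abs(Mod(compensate_iq(z, f)) - 1)), 1e-3)
  }
  # the ellipse center maps to the origin
  e <- structure(list(center = 0.3 + 0.2i, a = 2, b = 1, tilt = 0.3),
                 class = "rh_ellipse")
  expect_equal(compensate_iq(0.3 + 0.2i, e), 0 + 0i)
})

test_that("arctangent demodulation uses the [-pi, pi) branch", {
  expect_equal(demodulate_phase(1 + 0i), 0)
  expect_equal(demodulate_phase(0 + 1i), pi / 2)
  p <- demodulate_phase(complex(real = -1, imaginary = -1e-12))
  expect_lt(p, 0)
  expect_equal(p, -pi, tolerance = 1e-9)
  expect_equal(demodulate_phase(-1 + 0i), -pi)  # +pi folds to -pi
  expect_error(demodulate_phase(c(1 + 0i, 0 + 0i)),
               class = "radarheart_undefined_phase")
  expect_equal(demodulate_phase(c(1i, 0i, 2i), zero_policy = "hold"),
               c(pi / 2, pi / 2, pi / 2))
})

test_that("phase unwrapping corrects jumps beyond pi and round-trips", {
  w <- c(0, pi / 2, pi - 0.1, -pi + 0.1)
  expect_equal(unwrap_phase(w), c(0, pi / 2, pi - 0.1, pi + 0.1))
  expect_equal(unwrap_phase(rep(0.3, 5)), rep(0.3, 5))
  ramp <- seq(0, 6 * pi, length.out = 1000)
  wrapped <- radarheart:::wrap_to_pi(ramp)
  expect_equal(unwrap_phase(wrapped), ramp, tolerance = 1e-9)
  # idempotence and wrap-of-unwrap identity
  expect_equal(unwrap_phase(unwrap_phase(wrapped)), unwrap_phase(wrapped))
  expect_equal(radarheart:::wrap_to_pi(unwrap_phase(wrapped)), wrapped,
               tolerance = 1e-12)
})

test_that("phase converts to displacement via the half-wavelength scale", {
  expect_equal(phase_to_displacement(c(0, 0, 0), 24.17e9), c(0, 0, 0))
  dx <- phase_to_displacement(c(0, 2 * pi), 24.17e9)[2]
  expect_equal(dx, 299792458 / (2 * 24.17e9), tolerance = 1e-12)
  expect_equal(dx, 6.2015e-3, tolerance = 1e-4)
  expect_equal(phase_to_displacement(c(0, pi), 24.17e9)[2], dx / 2)
  # linearity in the phase
  phi <- c(0, 0.3, 1.1, -0.4)
  expect_equal(phase_to_displacement(3 * phi, 24.17e9),
               3 * phase_to_displacement(phi, 24.17e9))
})

test_that("full demodulation recovers synthetic displacement", {
  sc <- fixture_scene(seed = 11)
  gd <- generate_displacement(sc$config)
  xt <- gd$displacement$displacement
  xt <- xt - xt[1]
  err <- sqrt(mean((sc$disp$displacement - xt)^2)) / sqrt(mean(xt^2))
  expect_lt(err, 0.01)

  # noise-free case is essentially exact
  cfg0 <- scene_config(duration = 10, seed = 5, radar_noise = 0)
  gr0 <- generate_recording(cfg0)
  x0 <- generate_displacement(cfg0)$displacement$displacement
  x0 <- x0 - x0[1]
  d0 <- demodulate(gr0$recording)
  expect_lt(sqrt(mean((d0$displacement - x0)^2)) / sqrt(mean(x0^2)), 1e-6)
})

test_that("demodulation handles stationary and degenerate frames", {
  n <- 100
  fr <- tibble::tibble(b3 = rep(0.5, n), b4 = rep(0.2, n),
                       b5 = rep(0.9, n), b6 = rep(0.1, n))
  d <- demodulate(fr, carrier_freq = 24.17e9, fs = 2000)
  expect_equal(d$displacement, rep(0, n))
  # a trajectory with fewer than 5 distinct points cannot be compensated
  fr2 <- tibble::tibble(b3 = rep(c(0, 1), 10), b4 = 0,
                        b5 = rep(c(1, 0), 10), b6 = 0)
  expect_error(demodulate(fr2, carrier_freq = 24.17e9, fs = 2000),
               class = "radarheart_insufficient_data")
})

test_that("windowed ellipse refit stays consistent with the global fit", {
  cfg <- scene_config(duration = 12, seed = 9)
  gr <- generate_recording(cfg)
  dg <- demodulate(gr$recording)
  dw <- demodulate(gr$recording, refit_window = 4)
  # same waveform up to a small stitching error
  err <- sqrt(mean((dg$displacement - dw$displacement)^2)) /
    sqrt(mean(dg$displacement^2))
  expect_lt(err, 0.05)
})
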