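# Synthetic target waveforms and inlet-signal conversion.

test_that("PWSS target has exact mean, systolic peak, and strict positivity", {
  p <- make_pwss_target()
  expect_length(p$values, 80L)
  expect_equal(mean(p$values), 0.5, tolerance = 1e-9)
  expect_equal(p$times[which.max(p$values)], 0.11, tolerance = 1e-9)
  expect_equal(max(p$values), 1.5, tolerance = 1e-9)
  expect_true(all(p$values > 0))

  # zero pulse amplitude degenerates to a constant level
  flat <- make_pwss_target(period = 0.8, mean_wss = 0.5, pulse_amplitude = 0,
                           peak_time = 0.11, dt = 0.01)
  expect_equal(flat$values, rep(0.5, 80L))

  # different timing parameters still put the peak at peak_time
  p2 <- make_pwss_target(period = 1.0, peak_time = 0.25, dt = 0.005)
  expect_equal(p2$times[which.max(p2$values)], 0.25, tolerance = 1e-9)
})

test_that("PWSS generator rejects invalid parameter sets", {
  expect_error(make_pwss_target(mean_wss = 0.05, pulse_amplitude = 1),
               "not a valid high-PWSS target")
  expect_error(make_pwss_target(period = -1), "period")
  expect_error(make_pwss_target(dt = 0.013), "divide")
  expect_error(make_pwss_target(peak_time = 0.9), "peak_time")
})

test_that("OWSS target reverses sign and respects the mean bound", {
  o <- make_owss_target()
  expect_gte(stepwss:::count_sign_changes(o$values), 2L)
  expect_lte(abs(mean(o$values)), 0.02 + 1e-9)
  expect_lt(min(o$values), 0)
  expect_gt(max(o$values), 0)
  expect_equal(min(o$values), -0.02 - 0.1, tolerance = 1e-9)

  # single harmonic gives a pure zero-mean sinusoid
  s <- make_owss_target(mean_wss = 0, oscillation_amplitude = 0.1,
                        n_harmonics = 1L)
  expect_equal(mean(s$values), 0, tolerance = 1e-12)
  th <- 2 * pi * (s$times - 0.11) / 0.8
  expect_equal(s$values, -0.1 * cos(th), tolerance = 1e-12)

  expect_error(make_owss_target(mean_wss = -0.2,
                                oscillation_amplitude = 0.1),
               "not oscillatory")
})

test_that("waveforms are exactly cycle-periodic and scale linearly", {
  for (ts in list(make_pwss_target(), make_owss_target())) {
    t3 <- c(ts$times, ts$times + ts$period, ts$times + 2 * ts$period)
    v3 <- periodic_eval(ts, t3)
    expect_equal(round(v3, 12), round(rep(ts$values, 3L), 12))
  }
  # linearity of the Fourier construction
  a <- make_pwss_target(mean_wss = 0.5, pulse_amplitude = 1.0)
  b <- make_pwss_target(mean_wss = 1.5, pulse_amplitude = 3.0)
  expect_equal(b$values, 3 * a$values, tolerance = 1e-12)
})

test_that("flow-rate inversion matches hand evaluation and round-trips", {
  g <- channel_geometry(b1 = 4, h3 = 0.06, b2 = 5, h2 = 0.15)
  fl <- fluid_props(mu = 1e-3)
  tau <- time_series(c(0, 0.01), c(0.5, 0.5))
  Q <- flow_rate_from_pwss(tau, g, fl)
  expect_equal(Q$values, c(9.375e-9, 9.375e-9), tolerance = 1e-12)

  z <- flow_rate_from_pwss(time_series(c(0, 0.01), c(0, 0)), g, fl)
  expect_equal(z$values, c(0, 0))

  # Eq.-7 round trip is the identity on any waveform
  p <- make_pwss_target()
  back <- analytic_wss_partII(flow_rate_from_pwss(p, g, fl), g, fl)
  expect_equal(back$values, p$values, tolerance = 1e-12)
})

test_that("inlet signals match hand-computed plug speeds", {
  g <- channel_geometry(b1 = 4, h3 = 0.06, b2 = 5, h2 = 0.15, R = 0.5)
  Q <- time_series(c(0, 0.01), c(9.375e-9, 0))
  u2d <- inlet_signal_from_flow(Q, g, mode = "midplane_2d")
  expect_equal(u2d$values[1L], 9.375e-9 / (4e-3 * 0.09e-3), tolerance = 1e-6)
  expect_equal(u2d$values[1L], 0.026042, tolerance = 1e-4)
  expect_equal(u2d$values[2L], 0)
  u3d <- inlet_signal_from_flow(Q, g, mode = "circular_3d")
  expect_equal(u3d$values[1L], 0.011937, tolerance = 1e-4)
  expect_equal(u3d$values[2L], 0)
})

test_that("waveform CSV round-trips through disk", {
  p <- make_pwss_target()
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(p, path)
  r <- read_waveform_csv(path)
  expect_equal(r$values, p$values)
  expect_equal(r$times, p$times)
})
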