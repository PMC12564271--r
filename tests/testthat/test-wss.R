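# WSS extraction, observation sampling, streamfunction, vortex metrics.

test_that("zero flow gives zero wall WSS and zero streamfunction", {
  sf <- straight_field()
  f0 <- solve_steady(sf$grid, 0, fluid_props(), solver_config())
  prof <- wall_shear_bottom(f0, sf$grid, fluid_props())
  expect_true(all(prof$tau == 0))
  psi <- streamfunction(f0, sf$grid)
  expect_true(all(psi == 0))
})

test_that("analytic part II WSS matches hand evaluation and scales with b2", {
  g <- channel_geometry(b1 = 4, h3 = 0.06, b2 = 5, h2 = 0.15)
  fl <- fluid_props(mu = 1e-3)
  Q <- time_series(c(0, 0.01), c(1e-9, 0))
  tau <- analytic_wss_partII(Q, g, fl)
  expect_equal(tau$values[1L], 0.05333, tolerance = 1e-4)
  expect_equal(tau$values[2L], 0)
  g_half <- channel_geometry(b1 = 2.5, h3 = 0.06, b2 = 2.5, h2 = 0.15)
  tau2 <- analytic_wss_partII(Q, g_half, fl)
  expect_equal(tau2$values[1L], 2 * tau$values[1L], tolerance = 1e-12)
})

test_that("observation sampling is exact on linear data and checks bounds", {
  mk <- function(t) structure(
    list(x_mm = seq(14, 18, by = 0.5),
         tau = seq(14, 18, by = 0.5) * (1 + t), time = t),
    class = "wall_shear_profile")
  profiles <- list(mk(0), mk(0.01), mk(0.02))
  pts <- c(14.25, 15.1, 16.0, 17.33, 17.9)
  out <- sample_observation_series(profiles, pts)
  for (k in seq_along(pts)) {
    expect_equal(out[[k]]$values, pts[k] * (1 + c(0, 0.01, 0.02)),
                 tolerance = 1e-12)
  }
  # a point on a grid node returns the nodal value exactly
  expect_equal(sample_observation_series(profiles, 15)[[1L]]$values[1L], 15)
  expect_error(sample_observation_series(profiles, 13.5),
               "x = 13.5 mm outside")
})

test_that("streamfunction integrates Poiseuille flow to the flow rate", {
  sf <- straight_field()
  psi <- streamfunction(sf$field, sf$grid)
  # psi at the top wall equals the per-width flow rate everywhere
  expect_equal(max(abs(psi[, sf$grid$ny + 1L] - q_mean)) / q_mean, 0,
               tolerance = 1e-8)
  # d(psi)/dy reproduces u by construction
  du <- diff(t(psi))[, 1L] / sf$grid$dy[1L]
  expect_equal(du, sf$field$u[1L, ], tolerance = 1e-12)
})

test_that("vortex metrics: absent in a straight channel, present behind a step", {
  sf <- straight_field()
  vm0 <- vortex_metrics(sf$field, sf$grid, sf$geom, fluid_props())
  expect_false(vm0$exists)
  expect_equal(vm0$area_mm2, 0)
  expect_null(vm0$center_mm)

  st <- step_field()
  vm <- vortex_metrics(st$field, st$grid, st$grid$geometry, fluid_props())
  expect_true(vm$exists)
  expect_gt(vm$area_mm2, 0)
  expect_gt(vm$reattachment_mm, 0)
  # center sits downstream of the step, in the lower half of the channel
  expect_gt(vm$center_mm[1L], 14)
  expect_lt(vm$center_mm[2L], -0.075)
  # a closed psi < 0 region encircles the center
  psi <- streamfunction(st$field, st$grid)
  expect_lt(min(psi), 0)
})

test_that("vortex area grows with step height and with flow rate", {
  fl <- fluid_props()
  area_of <- function(h3, qscale) {
    g <- channel_geometry(b1 = 4, h3 = h3, b2 = 5)
    gr <- do.call(build_grid, c(list(g), list(base_dx = 5e-4,
                                              base_dy = 5e-6,
                                              refine_factor = 25)))
    f <- solve_steady(gr, q_mean * qscale, fl, solver_config())
    vortex_metrics(f, gr, g, fl)$area_mm2
  }
  a_low <- area_of(0.03, 3)
  a_high <- area_of(0.09, 3)
  expect_gt(a_high, a_low)
  # lower flow (the mean-flow instant) gives a smaller vortex than peak flow
  a_peak <- area_of(0.06, 3)
  a_mean <- area_of(0.06, 1)
  expect_lte(a_mean, a_peak)
})
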