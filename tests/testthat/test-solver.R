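# Flow solver: Stokes limit, Poiseuille oracle, mass conservation,
# pulsatile modes.

test_that("zero inflow gives the identically zero solution", {
  sf <- straight_field()
  f0 <- solve_steady(sf$grid, 0, fluid_props(), solver_config())
  expect_equal(max(abs(f0$u)), 0)
  expect_equal(max(abs(f0$v)), 0)
  expect_equal(max(abs(f0$p)), 0)
})

test_that("straight-channel solve develops plane Poiseuille flow", {
  sf <- straight_field()
  grid <- sf$grid; f <- sf$field
  # centerline-to-mean velocity ratio 3/2 downstream
  i <- which.min(abs(grid$xc - 20e-3))
  uprof <- f$u[i, ]
  expect_equal(max(uprof) / mean(uprof), 1.5, tolerance = 0.01)
  # bottom-wall WSS matches 6 mu q / h^2 within 2%
  prof <- wall_shear_bottom(f, grid, fluid_props())
  sel <- prof$x_mm > 15 & prof$x_mm < 20
  tau_ref <- 6 * 1e-3 * q_mean / (0.15e-3)^2
  expect_lt(max(abs(prof$tau[sel] / tau_ref - 1)), 0.02)
})

test_that("converged fields conserve mass; the residual is linear in a defect", {
  sf <- straight_field(); st <- step_field()
  expect_lt(mass_conservation_residual(sf$field, sf$grid), 1e-8)
  expect_lt(mass_conservation_residual(st$field, st$grid), 1e-8)
  # perturbing one interior u value grows the residual proportionally
  res <- vapply(c(1e-6, 1e-5), function(delta) {
    fp <- st$field
    i <- which.min(abs(st$grid$xf - 16e-3))
    fp$u[i, 10L] <- fp$u[i, 10L] + delta
    mass_conservation_residual(fp, st$grid)
  }, numeric(1))
  expect_equal(res[2L] / res[1L], 10, tolerance = 1e-3)
})

test_that("velocities scale linearly with flow rate in the creeping regime", {
  st <- step_field()
  q0 <- q_mean / 10   # Re ~ 0.2
  f1 <- solve_steady(st$grid, q0, fluid_props(), solver_config(),
                     workspace = st$ws)
  f2 <- solve_steady(st$grid, 2 * q0, fluid_props(), solver_config(),
                     workspace = st$ws)
  p1 <- wall_shear_bottom(f1, st$grid, fluid_props())
  p2 <- wall_shear_bottom(f2, st$grid, fluid_props())
  expect_lt(max(abs(p2$tau - 2 * p1$tau)) / max(abs(2 * p1$tau)), 0.01)
})

test_that("the step induces reversed near-wall flow at peak inflow", {
  st <- step_field()
  f <- solve_steady(st$grid, 3 * q_mean, fluid_props(), solver_config(),
                    workspace = st$ws)
  nx <- st$grid$nx
  uc <- 0.5 * (f$u[1:nx, ] + f$u[2:(nx + 1L), ])
  down <- st$grid$xc > st$grid$x_step
  expect_true(any(uc[down, ] < 0))
  # and the wall WSS is negative somewhere in the 14-17 mm band
  prof <- wall_shear_bottom(f, st$grid, fluid_props())
  band <- prof$x_mm >= 14 & prof$x_mm <= 17
  expect_lt(min(prof$tau[band]), 0)
})

test_that("transient modes handle zero flow and reach a limit cycle", {
  sf <- straight_field()
  Qz <- time_series(seq(0, 0.79, by = 0.01), rep(0, 80L), period = 0.8)
  fz <- solve_transient(sf$grid, Qz, sf$geom, fluid_props(),
                        solver_config(mode = "quasi_steady"))
  expect_true(all(vapply(fz, function(f) max(abs(f$u)), numeric(1)) == 0))

  Q <- flow_rate_from_pwss(make_pwss_target(), sf$geom, fluid_props())
  wss_series <- function(fields) {
    vapply(fields, function(f) {
      p <- wall_shear_bottom(f, sf$grid, fluid_props())
      stats::approx(p$x_mm, p$tau, xout = 20)$y
    }, numeric(1))
  }
  f2 <- suppressMessages(solve_transient(
    sf$grid, Q, sf$geom, fluid_props(),
    solver_config(mode = "unsteady", n_periods = 2)))
  f3 <- suppressMessages(solve_transient(
    sf$grid, Q, sf$geom, fluid_props(),
    solver_config(mode = "unsteady", n_periods = 3)))
  w2 <- wss_series(f2); w3 <- wss_series(f3)
  expect_lt(max(abs(w3 - w2)) / max(abs(w2)), 0.005)
})

test_that("flow diagnostics report the low-Womersley regime", {
  d <- flow_diagnostics(9.375e-9, channel_geometry(), fluid_props(),
                        period = 0.8)
  expect_equal(d$womersley, 0.21, tolerance = 0.01)
})
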