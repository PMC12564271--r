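# Shared fixtures, built lazily and cached for the whole test run.
#
# Two resolutions are used: `coarse_grid_opts` for unit checks (20 um cells
# at the step, 20 cells across h2) and `sweep_grid_opts` for the acceptance
# sweep (5 um cells at the step, 30 cells across h2, enough to resolve the
# h3 = 0.03 mm step).  The methods vignette records these choices.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

coarse_grid_opts <- list(base_dx = 5e-4, base_dy = 7.5e-6,
                         refine_factor = 25)
sweep_grid_opts <- list(base_dy = 5e-6, refine_factor = 50)

q_mean <- 2.34e-6   # per-width mean-flow scale of the default targets, m^2/s

ref_geometry <- function() channel_geometry(b1 = 4, h3 = 0.06, b2 = 5)

# steady solve of the reference step geometry at the mean-flow rate
step_field <- function() {
  fixture("step_field", {
    grid <- do.call(build_grid, c(list(ref_geometry()), coarse_grid_opts))
    f <- solve_steady(grid, q_mean, fluid_props(), solver_config())
    list(grid = grid, field = f, ws = attr(f, "workspace"))
  })
}

# steady straight-channel solve (no step)
straight_field <- function() {
  fixture("straight_field", {
    geom <- channel_geometry(b1 = 4, h3 = 0, b2 = 5)
    grid <- do.call(build_grid, c(list(geom), coarse_grid_opts))
    f <- solve_steady(grid, q_mean, fluid_props(), solver_config())
    list(geom = geom, grid = grid, field = f)
  })
}

# one coarse-resolution candidate evaluation of the reference design
eval_coarse <- function() {
  fixture("eval_coarse", {
    evaluate_design(ref_geometry(), make_pwss_target(), make_owss_target(),
                    grid_opts = coarse_grid_opts)
  })
}

# calibrated OWSS target at the sweep resolution
calibrated_target <- function() {
  fixture("calibrated_target", {
    calibrate_owss_target(make_pwss_target(), grid_opts = sweep_grid_opts)
  })
}

# full 18-candidate sweep (b2 = 5 and 4) at the sweep resolution
acceptance_sweep <- function() {
  fixture("acceptance_sweep", {
    sweep_optimize(sweep_spec(), make_pwss_target(), calibrated_target(),
                   fluid_props(), solver_config(),
                   grid_opts = sweep_grid_opts)
  })
}

sweep_row <- function(df, b1, h3, b2) {
  df[df$b1 == b1 & df$h3 == h3 & df$b2 == b2, , drop = FALSE]
}
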