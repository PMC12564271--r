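# Verification diagnostics: analytic oracles and grid convergence.

#' Steady wall-WSS error against the parallel-plate closed form
#'
#' Solves a straight (step-free) channel at per-width flow `q` and compares
#' the extracted bottom-wall WSS in a mid-channel window with the analytic
#' plane-Poiseuille value \eqn{6\mu q/h^2}.
#'
#' @param q Per-width flow rate in m^2/s (default the mean-flow scale of the
#'   default PWSS target, 2.34e-6).
#' @param h2 Channel height in mm (default 0.15).
#' @param fluid A [fluid_props()].
#' @param cfg A [solver_config()].
#' @param grid_opts Named list forwarded to [build_grid()].
#' @return List with `tau_sim` (mean simulated WSS over the window),
#'   `tau_analytic`, and `rel_err` (max relative deviation over the window).
#' @export
straight_channel_wss_check <- function(q = 2.34e-6, h2 = 0.15,
                                       fluid = fluid_props(),
                                       cfg = solver_config(),
                                       grid_opts = list(base_dx = 5e-4,
                                                        base_dy = 7.5e-6,
                                                        refine_factor = 10)) {
  geom <- channel_geometry(b1 = 4, h3 = 0, b2 = 5, h2 = h2)
  grid <- do.call(build_grid, c(list(geom), grid_opts))
  f <- solve_steady(grid, q, fluid, cfg)
  prof <- wall_shear_bottom(f, grid, fluid)
  sel <- prof$x_mm > 15 & prof$x_mm < 20
  tau_ref <- 6 * fluid$mu * q / (h2 * 1e-3)^2
  list(tau_sim = mean(prof$tau[sel]), tau_analytic = tau_ref,
       rel_err = max(abs(prof$tau[sel] / tau_ref - 1)))
}

#' Grid-convergence study of the wall WSS
#'
#' Observed convergence order of the straight-channel bottom-wall WSS
#' against the analytic plane-Poiseuille value under uniform refinement.
#' The leading discretization error of the developed discrete solution is
#' the midpoint quadrature of the parabolic flux profile, O(dy^2), so a
#' second-order scheme shows an observed order near 2.
#'
#' @param levels Refinement levels; both base cell sizes are divided by each
#'   level (default `c(1, 2, 4)`).
#' @param q Per-width flow rate in m^2/s.
#' @param h2 Channel height in mm (default 0.15).
#' @param base_dx,base_dy Level-1 cell sizes in m.
#' @param refine_factor Near-step refinement kept in the grid (fixed across
#'   levels; default 10).
#' @param fluid A [fluid_props()].
#' @param cfg A [solver_config()].
#' @return List with `levels`, `err` (relative WSS error per level), and
#'   `order` (observed order from the last three levels).
#' @export
wss_convergence_study <- function(levels = c(1, 2, 4), q = 2.34e-6,
                                  h2 = 0.15,
                                  base_dx = 5e-4, base_dy = 1.5e-5,
                                  refine_factor = 10,
                                  fluid = fluid_props(),
                                  cfg = solver_config()) {
  stopifnot(length(levels) >= 3L)
  err <- vapply(levels, function(l) {
    chk <- straight_channel_wss_check(
      q = q, h2 = h2, fluid = fluid, cfg = cfg,
      grid_opts = list(base_dx = base_dx / l, base_dy = base_dy / l,
                       refine_factor = refine_factor))
    abs(chk$tau_sim / chk$tau_analytic - 1)
  }, numeric(1))
  k <- length(levels)
  e1 <- err[k - 2L]; e2 <- err[k - 1L]; e3 <- err[k]
  r1 <- levels[k - 1L] / levels[k - 2L]
  r2 <- levels[k] / levels[k - 1L]
  order <- min(log(e1 / e2) / log(r1), log(e2 / e3) / log(r2))
  list(levels = levels, err = err, order = order)
}
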