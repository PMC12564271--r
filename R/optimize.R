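# RMSE-driven optimization of the step dimensions.
#
# The design loop mirrors the channel-design workflow: derive the inlet flow
# rate from the PWSS target by inverting the parallel-plate formula for the
# wide section, run the pulsatile solve for each candidate step geometry,
# sample the wall WSS at the five vortex-region observation points, score
# each candidate by the average RMSE against the OWSS target, and accept the
# first/best candidate under the design threshold (0.15 Pa).

#' Root mean square error between two waveforms
#'
#' \eqn{\sqrt{\mathrm{mean}((sim - target)^2)}} over the simulated samples.
#' If the two time grids differ, the target is resampled onto the simulated
#' grid by periodic linear interpolation.
#'
#' @param sim Simulated [time_series()] (Pa).
#' @param target Target [time_series()] (Pa).
#' @param normalized Divide by `max(abs(target))` (default FALSE, plain Pa).
#' @return RMSE in Pa (or dimensionless if `normalized`).
#' @export
rmse <- function(sim, target, normalized = FALSE) {
  stopifnot(inherits(sim, "time_series"), inherits(target, "time_series"))
  if (length(sim$values) == 0L) stop("empty overlap: no simulated samples")
  same <- length(sim$times) == length(target$times) &&
    all(abs(sim$times - target$times) < 1e-9)
  tv <- if (same) target$values else periodic_eval(target, sim$times)
  e <- sqrt(mean((sim$values - tv)^2))
  if (normalized) e <- e / max(abs(target$values))
  e
}

#' Sweep specification for the step-geometry search
#'
#' Default grid reflects the design protocol: step height in increments of
#' 0.03 mm, step width in increments of 1 mm, and the wide-section width
#' reduced from 5 to 4 mm to probe the flow-rate dependence; acceptance
#' threshold 0.15 on the average RMSE.
#'
#' @param b1 Step (part I) widths in mm (default `c(2, 3, 4)`).
#' @param h3 Step heights in mm (default `c(0.03, 0.06, 0.09)`).
#' @param b2 Part II widths in mm (default `c(5, 4)`).
#' @param threshold Average-RMSE acceptance bound in Pa (default 0.15).
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(b1 = c(2, 3, 4), h3 = c(0.03, 0.06, 0.09),
                       b2 = c(5, 4), threshold = 0.15) {
  if (!length(b1) || !length(h3) || !length(b2)) stop("empty sweep")
  if (any(b1 <= 0) || any(h3 <= 0) || any(b2 <= 0)) {
    stop("sweep values must be positive")
  }
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(b1 = as.numeric(b1), h3 = as.numeric(h3),
                 b2 = as.numeric(b2), threshold = as.numeric(threshold)),
            class = "sweep_spec")
}

#' Evaluate one candidate step geometry against the WSS targets
#'
#' Full design pipeline for a single geometry: invert the parallel-plate
#' formula to get Q(t) from the PWSS target, run the pulsatile mid-plane
#' solve, sample the wall WSS at the five vortex-region points, compute the
#' per-point and average RMSE against the OWSS target, characterize the
#' vortex at the peak-flow and mean-flow instants, and verify that the
#' part II section reproduces the PWSS target (per-width scaling `b1/b2`
#' accounts for the widening between the sections).
#'
#' @param geometry A [channel_geometry()].
#' @param pwss_target [time_series()] PWSS target (Pa) for part II.
#' @param owss_target [time_series()] OWSS target (Pa) for the vortex region.
#' @param fluid A [fluid_props()].
#' @param cfg A [solver_config()].
#' @param points An [observation_set()].
#' @param threshold Average-RMSE acceptance bound in Pa (default 0.15).
#' @param t_p,t_m Peak-flow and mean-flow evaluation times in s (defaults
#'   0.11 and 0.16).
#' @param grid_opts Named list of arguments forwarded to [build_grid()].
#' @param workspace Optional solver workspace reuse (same grid).
#' @return Object of class `design_result` with `rmse_per_point` (5 values,
#'   Pa), `rmse_avg`, `vortex` (metrics at `t_p` and `t_m`), `partII_rmse`
#'   (Pa), `partII_nrmse`, `criterion_met`, `vortex_wss_min` (most negative
#'   wall WSS over the cycle at the vortex-center x), and the sampled
#'   series; the
#'   solver workspace is attached as attribute `"workspace"`.
#' @export
evaluate_design <- function(geometry, pwss_target, owss_target,
                            fluid = fluid_props(), cfg = solver_config(),
                            points = observation_set(), threshold = 0.15,
                            t_p = 0.11, t_m = 0.16, grid_opts = list(),
                            workspace = NULL) {
  stopifnot(inherits(geometry, "channel_geometry"))
  Q <- flow_rate_from_pwss(pwss_target, geometry, fluid)
  grid <- do.call(build_grid, c(list(geometry), grid_opts))
  fields <- solve_transient(grid, Q, geometry, fluid, cfg,
                            workspace = workspace)
  ws <- attr(fields, "workspace")
  profiles <- lapply(fields, wall_shear_bottom, grid = grid, fluid = fluid)

  obs <- sample_observation_series(profiles, points$vortex_x,
                                   period = Q$period)
  rmse_pp <- vapply(obs, rmse, numeric(1), target = owss_target)
  rmse_avg <- mean(rmse_pp)

  # part II fidelity: simulated per-width WSS in the uniform section, scaled
  # by b1/b2 for the widening, against the PWSS target
  p2 <- sample_observation_series(profiles, points$partII_x,
                                  period = Q$period)
  scale <- geometry$b1 / geometry$b2
  p2_scaled <- lapply(p2, function(s) {
    time_series(s$times, s$values * scale, period = s$period,
                label = "wss_partII_sim")
  })
  partII_rmse <- mean(vapply(p2_scaled, rmse, numeric(1),
                             target = pwss_target))
  partII_nrmse <- partII_rmse / max(abs(pwss_target$values))

  k_p <- which.min(abs(Q$times - t_p))
  k_m <- which.min(abs(Q$times - t_m))
  vort <- list(
    t_p = vortex_metrics(fields[[k_p]], grid, geometry, fluid),
    t_m = vortex_metrics(fields[[k_m]], grid, geometry, fluid)
  )

  # WSS waveform at the (peak-flow) vortex center x, on the wall: its most
  # negative excursion measures the oscillation amplitude the step produces
  center_series <- NULL
  vortex_wss_min <- NA_real_
  if (vort$t_p$exists && !is.null(vort$t_p$center_mm)) {
    xc_mm <- unname(vort$t_p$center_mm[1L])
    center_series <- sample_observation_series(profiles, xc_mm,
                                               period = Q$period)[[1L]]
    vortex_wss_min <- min(center_series$values)
  }

  res <- structure(
    list(geometry = geometry, rmse_per_point = rmse_pp,
         rmse_avg = rmse_avg, vortex = vort,
         partII_rmse = partII_rmse, partII_nrmse = partII_nrmse,
         criterion_met = rmse_avg <= threshold, threshold = threshold,
         vortex_wss_min = vortex_wss_min,
         obs_series = obs, center_series = center_series,
         partII_series = p2_scaled,
         points = points),
    class = "design_result")
  attr(res, "workspace") <- ws
  res
}

#' @export
print.design_result <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "<design_result b1=%g h3=%g b2=%g mm: avg RMSE %.4g Pa (threshold %g) -> %s>\n",
    g$b1, g$h3, g$b2, x$rmse_avg, x$threshold,
    if (x$criterion_met) "ACCEPT" else "reject"))
  invisible(x)
}

#' Sweep the step dimensions and rank candidates by average RMSE
#'
#' Evaluates every combination in the [sweep_spec()] (optionally stopping at
#' the first candidate meeting the threshold) and returns the candidates
#' ranked by ascending average RMSE, ties broken by smaller `h3` then
#' smaller `b1`.  The pipeline is fully deterministic: identical inputs give
#' identical rankings regardless of evaluation order.  Solver factorizations
#' are shared between candidates with the same step height.
#'
#' @param spec A [sweep_spec()].
#' @param pwss_target,owss_target Target waveforms ([time_series()], Pa).
#' @param fluid A [fluid_props()].
#' @param cfg A [solver_config()].
#' @param points An [observation_set()].
#' @param geometry_base Named list of fixed geometry arguments (e.g. `h2`).
#' @param grid_opts Named list forwarded to [build_grid()].
#' @param early_stop Stop at the first candidate meeting the criterion
#'   (default FALSE, exhaustive).
#' @param verbose Print one line per candidate.
#' @return Object of class `design_sweep`: list with `results` (ranked
#'   [evaluate_design()] results), `best`, `spec`, `n_evaluated`.
#' @export
sweep_optimize <- function(spec, pwss_target, owss_target,
                           fluid = fluid_props(), cfg = solver_config(),
                           points = observation_set(),
                           geometry_base = list(), grid_opts = list(),
                           early_stop = FALSE, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  cand <- expand.grid(b1 = spec$b1, h3 = spec$h3, b2 = spec$b2,
                      KEEP.OUT.ATTRS = FALSE)
  ws_cache <- new.env(parent = emptyenv())
  results <- list()
  for (r in seq_len(nrow(cand))) {
    geom <- do.call(channel_geometry,
                    c(list(b1 = cand$b1[r], h3 = cand$h3[r],
                           b2 = cand$b2[r]), geometry_base))
    key <- sprintf("h3=%.10g", geom$h3)
    ws <- if (exists(key, envir = ws_cache)) get(key, envir = ws_cache) else
      NULL
    res <- evaluate_design(geom, pwss_target, owss_target, fluid, cfg,
                           points = points, threshold = spec$threshold,
                           grid_opts = grid_opts, workspace = ws)
    if (is.null(ws)) assign(key, attr(res, "workspace"), envir = ws_cache)
    attr(res, "workspace") <- NULL
    results[[length(results) + 1L]] <- res
    if (verbose) print(res)
    if (early_stop && res$criterion_met) break
  }
  ord <- order(vapply(results, function(x) x$rmse_avg, numeric(1)),
               vapply(results, function(x) x$geometry$h3, numeric(1)),
               vapply(results, function(x) x$geometry$b1, numeric(1)))
  results <- results[ord]
  structure(list(spec = spec, results = results, best = results[[1L]],
                 n_evaluated = length(results)),
            class = "design_sweep")
}

#' @export
print.design_sweep <- function(x, ...) {
  cat(sprintf("<design_sweep: %d candidates evaluated>\n", x$n_evaluated))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.design_sweep <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(b1 = r$geometry$b1, h3 = r$geometry$h3, b2 = r$geometry$b2,
               rmse_avg = r$rmse_avg, partII_rmse = r$partII_rmse,
               vortex_area_tp_mm2 = r$vortex$t_p$area_mm2,
               vortex_area_tm_mm2 = r$vortex$t_m$area_mm2,
               vortex_wss_min = r$vortex_wss_min,
               criterion_met = r$criterion_met)
  }))
}

#' Calibrate the OWSS target against a reference channel simulation
#'
#' The in-vivo OWSS target of the original design workflow came from a
#' patient-specific carotid simulation that is not reproducible here; this
#' function plays the same role synthetically.  It simulates the reference
#' channel geometry (by default the accepted design, step height 0.06 mm and
#' step width 4 mm with a 5 mm wide section), averages the wall-WSS series
#' over the five vortex-region observation points, and truncates it to a
#' Fourier series with `n_harmonics` harmonics.  The result is an
#' achievable, sign-reversing OWSS target on the WSS scale the device can
#' produce; the calibration parameters are recorded in the attribute
#' `"calibration"`.
#'
#' @param pwss_target [time_series()] PWSS target driving the flow.
#' @param reference_geometry A [channel_geometry()] (default the accepted
#'   design).
#' @param fluid A [fluid_props()].
#' @param cfg A [solver_config()].
#' @param points An [observation_set()].
#' @param n_harmonics Harmonics retained in the target (default 8).
#' @param grid_opts Named list forwarded to [build_grid()].
#' @return [time_series()] labelled `"owss_target"` with calibration
#'   metadata; errors with "not oscillatory" if the reference simulation
#'   does not produce a sign-reversing waveform.
#' @export
calibrate_owss_target <- function(pwss_target,
                                  reference_geometry = channel_geometry(
                                    b1 = 4, h3 = 0.06, b2 = 5),
                                  fluid = fluid_props(),
                                  cfg = solver_config(),
                                  points = observation_set(),
                                  n_harmonics = 8L, grid_opts = list()) {
  ref <- evaluate_design(reference_geometry, pwss_target,
                         owss_target = time_series(pwss_target$times,
                                                   numeric(length(pwss_target$times)),
                                                   period = pwss_target$period),
                         fluid = fluid, cfg = cfg, points = points,
                         grid_opts = grid_opts)
  series <- ref$obs_series
  v <- rowMeans(vapply(series, function(s) s$values,
                       numeric(length(series[[1L]]$values))))
  n <- length(v)
  if (n_harmonics >= n / 2) stop("n_harmonics too large for the sampling")
  co <- stats::fft(v) / n
  mean_level <- Re(co[1L])
  harm <- data.frame(
    k = seq_len(n_harmonics),
    amplitude = 2 * Mod(co[1L + seq_len(n_harmonics)]),
    phase = Arg(co[1L + seq_len(n_harmonics)])
  )
  wf <- cardiac_waveform(pwss_target$period, mean_level, harm,
                         label = "owss_target")
  ts <- sample_waveform(wf, pwss_target$dt)
  if (count_sign_changes(ts$values) < 2L) {
    stop("not oscillatory: reference simulation gave no sign-reversing WSS")
  }
  attr(ts, "calibration") <- list(
    reference_geometry = unclass(reference_geometry),
    n_harmonics = as.integer(n_harmonics),
    mean_level = mean_level,
    amplitude = max(abs(v - mean_level)),
    vortex_points_mm = points$vortex_x
  )
  ts
}
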