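# Wall shear stress extraction and vortex characterization.
#
# Bottom-wall WSS is tau = mu * du/dy evaluated at the local floor with a
# one-sided second-order stencil through the no-slip wall value; positive
# tau points in the +x flow direction, so reversed (recirculating) near-wall
# flow shows up as tau < 0.

#' Bottom-wall shear stress profile
#'
#' Evaluates \eqn{\tau_w(x) = \mu\,\partial u/\partial y} at the local bottom
#' wall (the part II floor `y = -h2` downstream of the step, the part I floor
#' `y = -(h2-h3)` upstream) using a one-sided second-order stencil through
#' the wall.  Quadratic velocity profiles (plane Poiseuille) are
#' differentiated exactly.
#'
#' @param field A `flow_field` from [solve_steady()] / [solve_transient()].
#' @param grid The [build_grid()] the field lives on.
#' @param fluid A [fluid_props()].
#' @return Object of class `wall_shear_profile`: list with `x_mm` (face
#'   positions, mm), `tau` (Pa, signed), `time` (s).  The single face at the
#'   step edge, where the floor level changes, is omitted.
#' @export
wall_shear_bottom <- function(field, grid, fluid = fluid_props()) {
  nx <- grid$nx; ny <- grid$ny
  dy <- grid$dy[1L]
  fluid_mask <- !grid$solid
  # bottom-most fluid cell per column
  jbot <- apply(fluid_mask, 1L, function(col) {
    w <- which(col)
    if (length(w)) w[1L] else NA_integer_
  })
  x <- numeric(0); tau <- numeric(0)
  for (i in seq_len(nx + 1L)) {
    jl <- if (i > 1L) jbot[i - 1L] else jbot[1L]
    jr <- if (i <= nx) jbot[i] else jbot[nx]
    if (is.na(jl) || is.na(jr) || jl != jr) next  # step edge / solid column
    j0 <- jl
    if (j0 + 1L > ny) next
    u1 <- field$u[i, j0]; u2 <- field$u[i, j0 + 1L]
    x <- c(x, grid$xf[i] * 1e3)
    tau <- c(tau, fluid$mu * (9 * u1 - u2) / (3 * dy))
  }
  structure(list(x_mm = x, tau = tau, time = field$time),
            class = "wall_shear_profile")
}

#' @export
as.data.frame.wall_shear_profile <- function(x, ...) {
  data.frame(x_mm = x$x_mm, tau_pa = x$tau)
}

#' Analytic quasi-steady WSS of the wide channel section
#'
#' Parallel-plate (wide rectangular duct) bottom-wall shear for a volumetric
#' flow rate Q through part II: \eqn{\tau_{w2}(t) = 6\mu Q(t)/(b_2 h_2^2)}.
#'
#' @param Q [time_series()] of flow rate in m^3/s.
#' @param geometry A [channel_geometry()].
#' @param fluid A [fluid_props()].
#' @return [time_series()] of WSS in Pa.
#' @export
analytic_wss_partII <- function(Q, geometry, fluid = fluid_props()) {
  stopifnot(inherits(Q, "time_series"))
  b2 <- geometry$b2 * 1e-3; h2 <- geometry$h2 * 1e-3
  if (b2 <= 0 || h2 <= 0) stop("b2 and h2 must be > 0")
  time_series(Q$times, 6 * fluid$mu * Q$values / (b2 * h2^2),
              period = Q$period, label = "wss_partII")
}

#' Observation point set
#'
#' Five wall points in the vortex region downstream of the step and five in
#' the uniform part II section, on the channel mid-axis at the floor.  The
#' vortex-region defaults sit just downstream of the step face (x = 14 mm),
#' inside the recirculation bubble of the reference geometry and within the
#' x = 14-17 mm band in which the wall WSS is evaluated.
#'
#' @param vortex_x Five distinct x-positions in mm within [14, 17].
#' @param partII_x Five distinct x-positions in mm in the part II section.
#' @return Object of class `observation_set`.
#' @export
observation_set <- function(vortex_x = c(14.032, 14.034, 14.036, 14.038,
                                         14.040),
                            partII_x = c(18, 19, 20, 21, 22)) {
  if (length(vortex_x) != 5L || anyDuplicated(vortex_x)) {
    stop("vortex_x must be 5 distinct positions")
  }
  if (any(vortex_x < 14 | vortex_x > 17)) {
    stop("vortex_x must lie within [14, 17] mm")
  }
  if (length(partII_x) != 5L || anyDuplicated(partII_x)) {
    stop("partII_x must be 5 distinct positions")
  }
  structure(list(vortex_x = sort(vortex_x), partII_x = sort(partII_x)),
            class = "observation_set")
}

#' Sample wall-WSS time series at observation points
#'
#' Linearly interpolates each per-time wall profile at the requested
#' x-positions and reassembles per-point time series.
#'
#' @param profiles List of [wall_shear_bottom()] profiles, one per time
#'   sample, with increasing `time`.
#' @param points Numeric vector of x-positions in mm (e.g. one block of an
#'   [observation_set()]).
#' @param period Optional cycle length passed to the returned series.
#' @return Named list of [time_series()], one per point (`"x14.02"`, ...).
#' @export
sample_observation_series <- function(profiles, points, period = NULL) {
  stopifnot(length(profiles) >= 2L)
  times <- vapply(profiles, function(p) p$time, numeric(1))
  vals <- vapply(profiles, function(p) {
    rng <- range(p$x_mm)
    bad <- points < rng[1L] | points > rng[2L]
    if (any(bad)) {
      stop(sprintf("observation point x = %g mm outside the wall profile",
                   points[which(bad)[1L]]))
    }
    stats::approx(p$x_mm, p$tau, xout = points)$y
  }, numeric(length(points)))
  vals <- matrix(vals, nrow = length(points))
  out <- lapply(seq_along(points), function(k) {
    time_series(times, vals[k, ], period = period, label = "wss_sampled")
  })
  names(out) <- sprintf("x%.5g", points)
  out
}

#' Streamfunction of a 2-D flow field
#'
#' Integrates \eqn{u = \partial\psi/\partial y} upward from the bottom
#' boundary (where \eqn{\psi = 0}) onto grid nodes.  Closed \eqn{\psi}
#' contours mark recirculation; the separating streamline leaving the step
#' corner carries \eqn{\psi = 0}.
#'
#' @param field A `flow_field`.
#' @param grid The [build_grid()] it lives on.
#' @param div_tol Maximum admissible mass-conservation residual (default
#'   1e-6); fields violating it are rejected.
#' @return Matrix `(nx+1) x (ny+1)` of streamfunction values (m^2/s) at grid
#'   nodes, with coordinates attached as attributes `x` and `y`.
#' @export
streamfunction <- function(field, grid, div_tol = 1e-6) {
  res <- mass_conservation_residual(field, grid)
  if (is.finite(res) && res > div_tol && max(abs(field$u)) > 0) {
    stop(sprintf("field is not divergence-free (residual %.3g)", res))
  }
  dy <- grid$dy[1L]
  psi <- matrix(0, grid$nx + 1L, grid$ny + 1L)
  for (j in seq_len(grid$ny)) {
    psi[, j + 1L] <- psi[, j] + field$u[, j] * dy
  }
  attr(psi, "x") <- grid$xf
  attr(psi, "y") <- grid$yf
  psi
}

#' Vortex metrics of the step recirculation zone
#'
#' Identifies the recirculation bubble downstream of the step as the
#' connected set of cells below the separating streamline (cell-averaged
#' \eqn{\psi < 0}, seeded at the \eqn{\psi} minimum), and reports its area,
#' center (the \eqn{\psi} extremum), and the reattachment length (distance
#' from the step face to the last sign change of the bottom-wall WSS).
#' Absence of a vortex is a valid result (`exists = FALSE`, zero area).
#'
#' @param field A `flow_field`.
#' @param grid The [build_grid()] it lives on.
#' @param geometry The [channel_geometry()].
#' @param fluid A [fluid_props()] (used for the wall-WSS sign change).
#' @return Object of class `vortex_metrics`: list with `exists`, `area_mm2`,
#'   `center_mm` (c(x, y) or NULL), `reattachment_mm`, `time`.
#' @export
vortex_metrics <- function(field, grid, geometry, fluid = fluid_props()) {
  nx <- grid$nx; ny <- grid$ny
  down <- grid$xc > grid$x_step          # cells strictly downstream
  fluid_mask <- !grid$solid

  # reversed streamwise flow (cell-centered u) downstream of the step
  uc <- 0.5 * (field$u[1:nx, , drop = FALSE] +
                 field$u[2:(nx + 1L), , drop = FALSE])
  umax <- max(abs(field$u))
  rev_tol <- if (umax > 0) 1e-8 * umax else 0
  reversed <- fluid_mask & down & (uc < -rev_tol)
  exists <- any(reversed)

  out <- structure(list(exists = exists, area_mm2 = 0, center_mm = NULL,
                        reattachment_mm = 0, time = field$time),
                   class = "vortex_metrics")
  if (!exists) return(out)

  psi <- streamfunction(field, grid)
  psic <- 0.25 * (psi[1:nx, 1:ny] + psi[2:(nx + 1L), 1:ny] +
                    psi[1:nx, 2:(ny + 1L)] + psi[2:(nx + 1L), 2:(ny + 1L)])
  psi_tol <- 1e-10 * max(abs(psi))
  neg <- fluid_mask & down & (psic < -psi_tol)
  if (any(neg)) {
    # connected component containing the psi minimum (the vortex core)
    seed <- which(neg & psic == min(psic[neg]))[1L]
    comp <- flood_component(neg, seed, nx, ny)
    area_cells <- outer(grid$dx, grid$dy)
    out$area_mm2 <- sum(area_cells[comp]) * 1e6
    core <- which(comp & psic == min(psic[comp]))[1L]
    ci <- (core - 1L) %% nx + 1L; cj <- (core - 1L) %/% nx + 1L
    out$center_mm <- c(x = grid$xc[ci] * 1e3, y = grid$yc[cj] * 1e3)
  }

  prof <- wall_shear_bottom(field, grid, fluid)
  sel <- prof$x_mm > grid$x_step * 1e3
  xs <- prof$x_mm[sel]; ts <- prof$tau[sel]
  negs <- which(ts < 0)
  if (length(negs)) {
    k <- negs[length(negs)]
    if (k < length(ts)) {
      # linear interpolation of the tau = 0 crossing
      x0 <- xs[k] - ts[k] * (xs[k + 1L] - xs[k]) / (ts[k + 1L] - ts[k])
    } else {
      x0 <- xs[k]
    }
    out$reattachment_mm <- max(0, x0 - grid$x_step * 1e3)
  }
  out
}

#' @export
print.vortex_metrics <- function(x, ...) {
  if (x$exists) {
    cat(sprintf(
      "<vortex at t = %g s: area %.4g mm^2, center (%.3f, %.4f) mm, reattachment %.4g mm>\n",
      x$time, x$area_mm2, x$center_mm[1L], x$center_mm[2L],
      x$reattachment_mm))
  } else {
    cat(sprintf("<no vortex at t = %g s>\n", x$time))
  }
  invisible(x)
}

# 4-connected component of `mask` containing linear index `seed`
flood_component <- function(mask, seed, nx, ny) {
  comp <- matrix(FALSE, nx, ny)
  comp[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    i <- (frontier - 1L) %% nx + 1L
    j <- (frontier - 1L) %/% nx + 1L
    nb <- c((i - 2L) + (j - 1L) * nx + 1L, i + (j - 1L) * nx + 1L,
            (i - 1L) + (j - 2L) * nx + 1L, (i - 1L) + j * nx + 1L)
    ok <- c(i > 1L, i < nx, j > 1L, j < ny)
    nb <- unique(nb[ok])
    nb <- nb[mask[nb] & !comp[nb]]
    comp[nb] <- TRUE
    frontier <- nb
  }
  comp
}
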