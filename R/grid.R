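# Staggered 2-D mid-plane grid for the stepped channel.
#
# Tensor-product Cartesian grid in SI units (m).  x is streamwise from the
# inlet, y vertical with the channel top at y = 0 and the part II floor at
# y = -h2.  The spacing is uniform in y and graded in x: uniform fine cells
# inside a refinement window bracketing the step, geometric growth (ratio
# <= `growth`) out to the base spacing elsewhere.  Cells are rasterized with
# half-open ownership: a cell is solid iff its center lies inside the step
# rectangle (y < -h2 + h3, x < x_step).

# Build one graded axis from 0 to L (m) with a uniform fine window [w0, w1].
graded_axis <- function(L, w0, w1, dx_fine, dx_coarse, growth = 1.3) {
  if (w0 <= 0 && w1 >= L) {
    n <- max(2L, as.integer(ceiling(L / dx_fine)))
    return(seq(0, L, length.out = n + 1L))
  }
  if (w1 <= 0 || w0 >= L || dx_fine >= dx_coarse) {
    n <- max(2L, as.integer(ceiling(L / dx_coarse)))
    return(seq(0, L, length.out = n + 1L))
  }
  w0 <- max(w0, 0); w1 <- min(w1, L)
  nf <- max(1L, as.integer(round((w1 - w0) / dx_fine)))
  faces_win <- seq(w0, w1, length.out = nf + 1L)
  grade_out <- function(span) {
    # spacings growing geometrically from dx_fine toward dx_coarse,
    # rescaled to fill `span` exactly
    if (span <= 0) return(numeric(0))
    d <- dx_fine
    sp <- numeric(0)
    while (sum(sp) < span) {
      d <- min(d * growth, dx_coarse)
      sp <- c(sp, d)
    }
    sp * (span / sum(sp))
  }
  left <- grade_out(w0)
  right <- grade_out(L - w1)
  faces <- c(w0 - rev(cumsum(rev(left))), faces_win,
             w1 + cumsum(right))
  faces[1L] <- 0
  faces[length(faces)] <- L
  faces
}

#' Build the staggered 2-D grid for a stepped channel
#'
#' Discretizes the mid-plane profile of a [channel_geometry()] on a
#' tensor-product staggered (MAC) grid: u on vertical cell faces, v on
#' horizontal faces, p at cell centers.  x-spacing is refined inside
#' `refine_window` (which must contain the step face); y-spacing is uniform.
#'
#' @param geometry A [channel_geometry()].
#' @param base_dx Coarse streamwise cell size in m (default 2.5e-4).
#' @param base_dy Vertical cell size in m (default 5e-6, i.e. 30 cells
#'   across `h2` = 0.15 mm).
#' @param refine_factor Ratio of coarse to fine streamwise spacing inside the
#'   window, >= 1 (default 100, i.e. 2.5 um cells at the step).
#' @param refine_window Streamwise window in mm refined around the step
#'   (default `c(13.5, 14.5)`).
#' @param growth Maximum ratio between adjacent cell sizes in the graded
#'   region (default 1.3).
#' @return Object of class `grid2d` with fields `xf`, `yf` (face
#'   coordinates, m), `xc`, `yc` (cell centers), `dx`, `dy`, `nx`, `ny`,
#'   `solid` (nx x ny logical mask), `cell_type` (nx x ny character:
#'   `"fluid"`, `"solid"`, `"inlet"`, `"outlet"`, `"wall"`), `x_step`
#'   (snapped step-face position, m), and the generating parameters.
#' @export
build_grid <- function(geometry, base_dx = 2.5e-4, base_dy = 5e-6,
                       refine_factor = 100, refine_window = c(13.5, 14.5),
                       growth = 1.3) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (base_dx <= 0 || base_dy <= 0) stop("base cell sizes must be positive")
  if (refine_factor < 1) stop("refine_factor must be >= 1")
  L <- geometry$L_total * 1e-3
  h2 <- geometry$h2 * 1e-3
  h3 <- geometry$h3 * 1e-3
  x_step <- geometry$x_step * 1e-3
  win <- sort(refine_window) * 1e-3
  if (h3 > 0 && (x_step < win[1L] || x_step > win[2L])) {
    stop("refine_window must contain x_step")
  }
  dx_fine <- base_dx / refine_factor
  xf <- graded_axis(L, win[1L], win[2L], dx_fine, base_dx, growth)
  ny <- max(2L, as.integer(round(h2 / base_dy)))
  yf <- seq(-h2, 0, length.out = ny + 1L)
  nx <- length(xf) - 1L
  xc <- (xf[-1L] + xf[-length(xf)]) / 2
  yc <- (yf[-1L] + yf[-length(yf)]) / 2
  dx <- diff(xf)
  dy <- diff(yf)

  # snap the step face to the nearest x face, rasterize by cell centers
  i_step <- which.min(abs(xf - x_step))
  x_step_snap <- xf[i_step]
  solid <- matrix(FALSE, nx, ny)
  if (h3 > 0) {
    j_solid <- which(yc < -h2 + h3)
    if (length(j_solid) < 6L) {
      stop("insufficient step resolution: need >= 6 cells across h3")
    }
    solid[seq_len(i_step - 1L), j_solid] <- TRUE
  }

  # connectivity: every fluid cell reachable from the inlet column
  fluid <- !solid
  reach <- matrix(FALSE, nx, ny)
  reach[1L, fluid[1L, ]] <- TRUE
  frontier <- which(reach)
  while (length(frontier)) {
    i <- (frontier - 1L) %% nx + 1L
    j <- (frontier - 1L) %/% nx + 1L
    nb <- c((i - 2L) + (j - 1L) * nx + 1L, i + (j - 1L) * nx + 1L,
            (i - 1L) + (j - 2L) * nx + 1L, (i - 1L) + j * nx + 1L)
    ok <- c(i > 1L, i < nx, j > 1L, j < ny)
    nb <- nb[ok]
    nb <- nb[fluid[nb] & !reach[nb]]
    nb <- unique(nb)
    reach[nb] <- TRUE
    frontier <- nb
  }
  if (any(fluid & !reach)) {
    stop("grid mask is disconnected: fluid cells unreachable from inlet")
  }

  cell_type <- matrix("fluid", nx, ny)
  cell_type[solid] <- "solid"
  # wall-adjacent fluid cells (top/bottom boundaries or next to solid)
  for (i in seq_len(nx)) {
    js <- which(fluid[i, ])
    if (!length(js)) next
    cell_type[i, min(js)] <- "wall"
    cell_type[i, max(js)] <- "wall"
  }
  if (h3 > 0 && i_step > 1L && i_step <= nx) {
    j_solid <- which(yc < -h2 + h3)
    jj <- j_solid[fluid[i_step, j_solid]]  # fluid cells facing the step
    cell_type[i_step, jj] <- "wall"
  }
  cell_type[1L, fluid[1L, ]] <- "inlet"
  cell_type[nx, fluid[nx, ]] <- "outlet"

  structure(
    list(xf = xf, yf = yf, xc = xc, yc = yc, dx = dx, dy = dy,
         nx = nx, ny = ny, solid = solid, cell_type = cell_type,
         x_step = x_step_snap, i_step = i_step, geometry = geometry,
         base_dx = base_dx, base_dy = base_dy,
         refine_factor = refine_factor, refine_window = refine_window,
         growth = growth),
    class = "grid2d"
  )
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf(
    "<grid2d: %d x %d cells (%d fluid), dx in [%.3g, %.3g] m, dy = %.3g m>\n",
    x$nx, x$ny, sum(!x$solid), min(x$dx), max(x$dx), x$dy[1L]))
  invisible(x)
}

#' Fluid area of the discretized mid-plane
#'
#' Total area of fluid cells, for checking mask consistency against the
#' analytic mid-plane polygon area `L_total*h2 - x_step*h3`.
#'
#' @param grid A [build_grid()] result.
#' @return List with `discrete` and `analytic` areas in m^2 and `max_cell`
#'   (largest single cell area, the rasterization tolerance).
#' @export
fluid_area <- function(grid) {
  area_cells <- outer(grid$dx, grid$dy)
  discrete <- sum(area_cells[!grid$solid])
  g <- grid$geometry
  analytic <- g$L_total * 1e-3 * g$h2 * 1e-3 - grid$x_step * g$h3 * 1e-3
  list(discrete = discrete, analytic = analytic,
       max_cell = max(area_cells))
}
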