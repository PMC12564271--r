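# Parameterization of the stepped variable cross-section channel.
#
# The chamber has two rectangular sections: a narrow part I (width b1,
# height h1) carrying a floor step of height h3 near its end, and a wide
# part II (width b2, height h2) joined by a short transition.  The step is a
# backward-facing step on the floor: upstream floor at y = -(h2 - h3),
# downstream floor at y = -h2, channel top at y = 0.  All stored dimensions
# are in mm (the units the device is specified in); solver-facing code
# converts to SI.

#' Fluid properties
#'
#' @param mu Dynamic viscosity in Pa.s (default 1e-3, water-like culture
#'   medium).
#' @param rho Density in kg/m^3 (default 1000).
#' @return Object of class `fluid_props`.
#' @export
fluid_props <- function(mu = 1e-3, rho = 1000) {
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  structure(list(mu = as.numeric(mu), rho = as.numeric(rho)),
            class = "fluid_props")
}

#' Stepped-channel geometry
#'
#' All dimensions in mm.  The part I height is derived from the step:
#' `h1 = h2 - h3`.
#'
#' @param b1 Part I width (default 4).
#' @param h3 Step height; must be < `h2` (default 0.06).
#' @param b2 Part II width (default 5); must be >= `b1`.
#' @param h2 Part II height (default 0.15).
#' @param L1 Part I length (default 13.5).
#' @param L2 Part II length (default 10).
#' @param L_trans Transition length between parts (default 1).
#' @param R Inlet/outlet port radius (default 0.5).
#' @param x_step Streamwise position of the step face (default 14).
#' @return Object of class `channel_geometry` with the derived field `h1`
#'   and total length `L_total = L1 + L_trans + L2`.
#' @export
channel_geometry <- function(b1 = 4, h3 = 0.06, b2 = 5, h2 = 0.15,
                             L1 = 13.5, L2 = 10, L_trans = 1, R = 0.5,
                             x_step = 14) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("%s must be a single finite number", nm))
    }
    as.numeric(x)
  }
  g <- list(b1 = num1(b1, "b1"), h3 = num1(h3, "h3"), b2 = num1(b2, "b2"),
            h2 = num1(h2, "h2"), L1 = num1(L1, "L1"), L2 = num1(L2, "L2"),
            L_trans = num1(L_trans, "L_trans"), R = num1(R, "R"),
            x_step = num1(x_step, "x_step"))
  pos <- c("b1", "b2", "h2", "L1", "L2", "L_trans", "R")
  for (nm in pos) if (g[[nm]] <= 0) stop(sprintf("%s must be > 0", nm))
  if (g$h3 < 0) stop("h3 must be >= 0")
  if (g$h3 >= g$h2) stop("h3 must be < h2")
  if (g$b1 > g$b2) stop("b1 must be <= b2")
  g$h1 <- g$h2 - g$h3
  g$L_total <- g$L1 + g$L_trans + g$L2
  if (g$x_step < 0 || g$x_step > g$L_total) {
    stop("x_step must lie inside [0, L1 + L_trans + L2]")
  }
  structure(g, class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("<channel_geometry [mm]: part I %gx%g (L=%g), step h3=%g at ",
           "x=%g, part II %gx%g (L=%g), transition %g, port R=%g>\n"),
    x$b1, x$h1, x$L1, x$h3, x$x_step, x$b2, x$h2, x$L2, x$L_trans, x$R))
  invisible(x)
}

#' Build a validated geometry from a configuration list
#'
#' Accepts a named list (e.g. the `geometry` block of a run config) holding
#' at least `b1`, `h3`, `b2`, `h2`; remaining dimensions take their defaults.
#' `h1` is always derived as `h2 - h3`.
#'
#' @param config Named list of dimensions in mm.
#' @return A [channel_geometry()].
#' @export
build_geometry <- function(config) {
  if (!is.list(config)) stop("config must be a named list")
  allowed <- names(formals(channel_geometry))
  unknown <- setdiff(names(config), c(allowed, "h1"))
  if (length(unknown)) {
    stop(sprintf("unknown geometry keys: %s", paste(unknown, collapse = ", ")))
  }
  config$h1 <- NULL   # always derived
  do.call(channel_geometry, config)
}
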