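# Synthetic cardiac waveform targets and their conversion to inlet signals.
#
# The in-vivo target waveforms (patient carotid, ultrasound-driven) are not
# available as data; a truncated Fourier family with a von-Mises-shaped
# systolic pulse stands in for them.  All waveforms are periodic scalar
# signals sampled over exactly one cardiac cycle.

#' Uniformly sampled periodic time series
#'
#' Container for one cardiac cycle of a scalar signal (wall shear stress in
#' Pa, volumetric flow rate in m^3/s, or velocity in m/s) sampled on a
#' uniform time grid.
#'
#' @param times Sample times in seconds, strictly increasing, uniformly
#'   spaced, length >= 2.
#' @param values Scalar signal values at `times`.
#' @param period Cycle length in seconds (defaults to the grid span plus one
#'   step, i.e. samples cover `[0, period)`).
#' @param label Optional label, e.g. `"pwss_target"`, `"owss_target"`,
#'   `"flow_rate"`.
#' @return An object of class `time_series` with fields `times`, `values`,
#'   `dt`, `period`, `label`.
#' @export
time_series <- function(times, values, period = NULL, label = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L) stop("time_series needs at least 2 samples")
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  dts <- diff(times)
  if (any(dts <= 0)) stop("times must be strictly increasing")
  dt <- dts[1L]
  if (any(abs(dts - dt) > 1e-9 * dt)) stop("times must be uniformly spaced")
  if (is.null(period)) period <- times[length(times)] - times[1L] + dt
  structure(
    list(times = times, values = values, dt = dt,
         period = as.numeric(period), label = label),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series%s: %d samples, dt = %g s, period = %g s, range [%.4g, %.4g]>\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    length(x$times), x$dt, x$period, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' Periodic cardiac waveform (Fourier parameterization)
#'
#' A cycle-periodic scalar waveform
#' \deqn{w(t) = m + \sum_k a_k \cos(2\pi k t / T + \phi_k)}
#' used to parameterize target wall-shear-stress and flow-rate signals.
#'
#' @param period Cycle length T in seconds, > 0.
#' @param mean_level Cycle-mean level m (Pa for WSS targets, m^3/s for flow).
#' @param harmonics Data frame with columns `k` (harmonic index, positive
#'   integers), `amplitude` and `phase` (radians); may have zero rows.
#' @param label One of `"pwss_target"`, `"owss_target"`, `"flow_rate"`, or
#'   `NULL`.
#' @return Object of class `cardiac_waveform`.
#' @export
cardiac_waveform <- function(period, mean_level, harmonics = NULL,
                             label = NULL) {
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  if (is.null(harmonics)) {
    harmonics <- data.frame(k = integer(), amplitude = numeric(),
                            phase = numeric())
  }
  stopifnot(all(c("k", "amplitude", "phase") %in% names(harmonics)))
  if (nrow(harmonics) && any(harmonics$k < 1)) {
    stop("harmonic indices must be positive")
  }
  structure(
    list(period = as.numeric(period), mean_level = as.numeric(mean_level),
         harmonics = harmonics, label = label),
    class = "cardiac_waveform"
  )
}

#' Evaluate a cardiac waveform at arbitrary times
#'
#' @param w A [cardiac_waveform()].
#' @param t Times in seconds (any real values; the waveform is periodic).
#' @return Numeric vector of waveform values.
#' @export
eval_waveform <- function(w, t) {
  stopifnot(inherits(w, "cardiac_waveform"))
  v <- rep(w$mean_level, length(t))
  if (nrow(w$harmonics)) {
    for (r in seq_len(nrow(w$harmonics))) {
      v <- v + w$harmonics$amplitude[r] *
        cos(2 * pi * w$harmonics$k[r] * t / w$period + w$harmonics$phase[r])
    }
  }
  v
}

#' Sample a cardiac waveform over one period
#'
#' @param w A [cardiac_waveform()].
#' @param dt Sampling step in seconds; must divide the period.
#' @return A [time_series()] covering `[0, period)` with the waveform object
#'   attached as attribute `"waveform"`.
#' @export
sample_waveform <- function(w, dt) {
  stopifnot(inherits(w, "cardiac_waveform"))
  n <- check_dt_divides(w$period, dt)
  tt <- seq(0, by = dt, length.out = n)
  ts <- time_series(tt, eval_waveform(w, tt), period = w$period,
                    label = w$label)
  attr(ts, "waveform") <- w
  ts
}

check_dt_divides <- function(period, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  n <- period / dt
  if (abs(n - round(n)) > 1e-8) stop("dt must divide the period exactly")
  as.integer(round(n))
}

# Fourier coefficients of a von-Mises pulse exp(conc*(cos(theta)-1)):
# relative harmonic weights I_k(conc)/I_0(conc), k = 1..n.
vonmises_weights <- function(conc, n_harmonics) {
  if (conc <= 0) stop("concentration must be > 0")
  besselI(conc, seq_len(n_harmonics), expon.scaled = TRUE) /
    besselI(conc, 0, expon.scaled = TRUE)
}

#' Synthetic high-PWSS target waveform
#'
#' Generates a strictly positive, cycle-periodic pulsatile wall shear stress
#' target with a single dominant systolic peak, of the kind measured in the
#' healthy downstream segment of the carotid bifurcation.  The shape is a
#' truncated Fourier series of a von Mises pulse centered at `peak_time`,
#' normalized so the sampled cycle mean equals `mean_wss` exactly and the
#' peak value equals `mean_wss + pulse_amplitude`.
#'
#' @param period Cardiac period in seconds (default 0.8 s).
#' @param mean_wss Cycle-mean WSS in Pa, > 0 (default 0.5 Pa).
#' @param pulse_amplitude Peak WSS above the mean, in Pa (default 1.0 Pa,
#'   i.e. peak ~ 1.5 Pa).
#' @param peak_time Systolic peak time t_p in seconds, in (0, period)
#'   (default 0.11 s).
#' @param n_harmonics Number of Fourier harmonics retained (default 8).
#' @param dt Sampling step in seconds; must divide `period` (default 0.01 s).
#' @param concentration Sharpness of the systolic pulse (von Mises
#'   concentration; default 10 gives a systole of roughly a quarter cycle).
#' @return [time_series()] labelled `"pwss_target"`, one period at `dt`.
#' @export
make_pwss_target <- function(period = 0.8, mean_wss = 0.5,
                             pulse_amplitude = 1.0, peak_time = 0.11,
                             n_harmonics = 8L, dt = 0.01,
                             concentration = 10) {
  n <- check_dt_divides(period, dt)
  if (mean_wss <= 0) stop("mean_wss must be > 0")
  if (peak_time <= 0 || peak_time >= period) {
    stop("peak_time must lie in (0, period)")
  }
  if (pulse_amplitude < 0) stop("pulse_amplitude must be >= 0")
  if (n_harmonics >= n / 2) {
    stop("n_harmonics must be < period/(2*dt) to avoid aliasing")
  }
  if (n_harmonics >= 1L && pulse_amplitude > 0) {
    w <- vonmises_weights(concentration, n_harmonics)
    scale <- pulse_amplitude / (2 * sum(w))     # peak of the pulse shape is 1
    harm <- data.frame(
      k = seq_len(n_harmonics),
      amplitude = 2 * w * scale,
      phase = -2 * pi * seq_len(n_harmonics) * peak_time / period
    )
  } else {
    harm <- NULL
  }
  wf <- cardiac_waveform(period, mean_wss, harm, label = "pwss_target")
  ts <- sample_waveform(wf, dt)
  if (any(ts$values <= 0)) {
    stop("not a valid high-PWSS target: parameters produce non-positive WSS")
  }
  ts
}

#' Synthetic low-OWSS target waveform
#'
#' Generates a low-magnitude, sign-reversing (oscillatory) wall shear stress
#' target of the kind found in the recirculating flow at a stenosed carotid
#' sinus: a negative excursion synchronized with systole and a weak positive
#' phase in diastole.  The sampled cycle mean equals `mean_wss` exactly and
#' the systolic extreme equals `mean_wss - oscillation_amplitude`.
#'
#' @param period Cardiac period in seconds (default 0.8 s).
#' @param mean_wss Cycle-mean WSS in Pa (default -0.02 Pa); must satisfy
#'   `abs(mean_wss) < oscillation_amplitude`.
#' @param oscillation_amplitude Magnitude of the systolic excursion below the
#'   mean, in Pa (default 0.1 Pa).
#' @param n_harmonics Number of Fourier harmonics (default 8; 1 gives a pure
#'   sinusoid).
#' @param dt Sampling step in seconds (default 0.01 s).
#' @param peak_time Time of the negative systolic extreme (default 0.11 s).
#' @param concentration Pulse sharpness (default 3; broader than the PWSS
#'   pulse, reflecting the smeared reversal at the sinus).
#' @return [time_series()] labelled `"owss_target"`; guaranteed to cross zero
#'   at least twice per period.
#' @export
make_owss_target <- function(period = 0.8, mean_wss = -0.02,
                             oscillation_amplitude = 0.1, n_harmonics = 8L,
                             dt = 0.01, peak_time = 0.11, concentration = 3) {
  n <- check_dt_divides(period, dt)
  if (oscillation_amplitude <= 0) stop("oscillation_amplitude must be > 0")
  if (abs(mean_wss) >= oscillation_amplitude) {
    stop("not oscillatory: need abs(mean_wss) < oscillation_amplitude")
  }
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (n_harmonics >= n / 2) {
    stop("n_harmonics must be < period/(2*dt) to avoid aliasing")
  }
  if (n_harmonics == 1L) {
    # pure sinusoid, negative extreme at peak_time
    harm <- data.frame(k = 1L, amplitude = oscillation_amplitude,
                       phase = pi - 2 * pi * peak_time / period)
  } else {
    w <- vonmises_weights(concentration, n_harmonics)
    scale <- -oscillation_amplitude / (2 * sum(w)) # invert: dip at systole
    harm <- data.frame(
      k = seq_len(n_harmonics),
      amplitude = abs(2 * w * scale),
      phase = pi - 2 * pi * seq_len(n_harmonics) * peak_time / period
    )
  }
  wf <- cardiac_waveform(period, mean_wss, harm, label = "owss_target")
  ts <- sample_waveform(wf, dt)
  if (count_sign_changes(ts$values) < 2L) {
    stop("not oscillatory: waveform does not reverse sign twice per period")
  }
  ts
}

# Sign changes over one period, treating the series as circular.
count_sign_changes <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s != c(s[-1L], s[1L]))
}

#' Inlet volumetric flow rate from a PWSS target
#'
#' Inverts the quasi-steady parallel-plate wall-shear formula for the wide
#' downstream channel section, \eqn{\tau = 6 \mu Q / (b_2 h_2^2)}, to obtain
#' the volumetric flow rate that reproduces a target PWSS there:
#' \deqn{Q(t) = \tau(t)\, b_2 h_2^2 / (6\mu).}
#'
#' @param target [time_series()] of target WSS in Pa.
#' @param geometry A [channel_geometry()] (uses `b2`, `h2`, in mm).
#' @param fluid A [fluid_props()].
#' @return [time_series()] of flow rate in m^3/s, labelled `"flow_rate"`.
#' @export
flow_rate_from_pwss <- function(target, geometry, fluid = fluid_props()) {
  stopifnot(inherits(target, "time_series"))
  b2 <- geometry$b2 * 1e-3
  h2 <- geometry$h2 * 1e-3
  if (b2 <= 0 || h2 <= 0) stop("b2 and h2 must be > 0")
  if (fluid$mu <= 0) stop("viscosity must be > 0")
  time_series(target$times, target$values * b2 * h2^2 / (6 * fluid$mu),
              period = target$period, label = "flow_rate")
}

#' Inlet boundary signal from a flow-rate waveform
#'
#' Converts a volumetric flow rate into the inlet velocity boundary signal:
#' either the magnitude of the uniform velocity through the circular inlet
#' port, \eqn{|V_i|(t) = Q(t)/(\pi R^2)}, or the per-width uniform plug speed
#' used by the 2-D mid-plane solver, \eqn{u_{in}(t) = Q(t)/(b_1 h_1)}.
#'
#' @param Q [time_series()] of flow rate in m^3/s.
#' @param geometry A [channel_geometry()].
#' @param mode `"midplane_2d"` (default) or `"circular_3d"`.
#' @return [time_series()] of inlet speed in m/s.
#' @export
inlet_signal_from_flow <- function(Q, geometry,
                                   mode = c("midplane_2d", "circular_3d")) {
  stopifnot(inherits(Q, "time_series"))
  mode <- match.arg(mode)
  if (mode == "circular_3d") {
    R <- geometry$R * 1e-3
    if (R <= 0) stop("port radius R must be > 0")
    v <- Q$values / (pi * R^2)
  } else {
    b1 <- geometry$b1 * 1e-3
    h1 <- geometry$h1 * 1e-3
    if (b1 <= 0 || h1 <= 0) stop("b1 and h1 must be > 0")
    v <- Q$values / (b1 * h1)
  }
  time_series(Q$times, v, period = Q$period, label = "inlet_velocity")
}

#' Evaluate a periodic time series at arbitrary times
#'
#' Linear interpolation with exact periodic wrap-around; evaluating over k
#' periods yields k identical copies of the one-cycle samples.
#'
#' @param ts A [time_series()].
#' @param t Times in seconds (any real values).
#' @return Numeric vector of interpolated values.
#' @export
periodic_eval <- function(ts, t) {
  stopifnot(inherits(ts, "time_series"))
  tw <- (t - ts$times[1L]) %% ts$period + ts$times[1L]
  # wrap samples: append the first sample at t0 + period for interpolation
  xs <- c(ts$times, ts$times[1L] + ts$period)
  ys <- c(ts$values, ts$values[1L])
  stats::approx(xs, ys, xout = tw, rule = 2)$y
}

#' Write / read a waveform as two-column CSV
#'
#' Plain-text interchange format: header `time_s,value`, one row per sample.
#'
#' @param ts A [time_series()].
#' @param path File path.
#' @return `write_waveform_csv` returns `path` invisibly; `read_waveform_csv`
#'   returns a [time_series()].
#' @export
write_waveform_csv <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d))) {
    stop("waveform CSV must have columns time_s,value")
  }
  time_series(d$time_s, d$value)
}
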