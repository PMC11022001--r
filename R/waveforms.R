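#' Cardiac waveform specification
#'
#' Parameterizes the simplified pulsatile inlet-velocity / outlet-pressure
#' waveforms applied to the parent artery: a half-sine (squared) systolic
#' peak over a diastolic baseline, with exact closed-form control of the
#' systole-peak value and the cycle period. Time zero is start-systole; the
#' systole peak occurs at \code{systole_fraction * period / 2}.
#'
#' @param heart_rate Heart rate, beats/min. Not fixed by the imaging
#'   protocol; the default 240 beats/min is typical of an anesthetized New
#'   Zealand white rabbit.
#' @param peak_velocity Inlet velocity at the systole peak, m/s.
#' @param outlet_pressure_min,outlet_pressure_max Outlet pressure range, Pa
#'   (defaults 5732 and 13865 Pa, i.e. 43-104 mmHg).
#' @param n_samples_per_cycle Uniform samples per cardiac cycle.
#' @param systole_fraction Fraction of the cycle occupied by systole.
#' @param diastolic_velocity_fraction Diastolic baseline velocity as a
#'   fraction of \code{peak_velocity}.
#' @return An object of class \code{waveform_spec}; \code{period} is
#'   \code{60 / heart_rate} seconds.
#' @export
waveform_spec <- function(heart_rate = 240,
                          peak_velocity = 0.35,
                          outlet_pressure_min = 5732,
                          outlet_pressure_max = 13865,
                          n_samples_per_cycle = 200,
                          systole_fraction = 0.35,
                          diastolic_velocity_fraction = 0.2) {
  if (heart_rate <= 0) stop("heart_rate must be > 0 beats/min")
  if (peak_velocity <= 0) stop("peak_velocity must be > 0 m/s")
  if (n_samples_per_cycle < 4) stop("n_samples_per_cycle must be >= 4")
  if (outlet_pressure_min >= outlet_pressure_max)
    stop("outlet_pressure_min must be < outlet_pressure_max")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("systole_fraction must lie in (0, 1)")
  structure(list(
    heart_rate = heart_rate,
    peak_velocity = peak_velocity,
    period = 60 / heart_rate,
    outlet_pressure_min = outlet_pressure_min,
    outlet_pressure_max = outlet_pressure_max,
    n_samples_per_cycle = as.integer(n_samples_per_cycle),
    systole_fraction = systole_fraction,
    diastolic_velocity_fraction = diastolic_velocity_fraction
  ), class = "waveform_spec")
}

#' Time of the systole peak
#'
#' @param spec A \code{\link{waveform_spec}}.
#' @param cycle 0-based cardiac-cycle index.
#' @return Time in seconds of the inlet-velocity maximum of that cycle.
#' @export
systole_peak_time <- function(spec, cycle = 0) {
  stopifnot(inherits(spec, "waveform_spec"))
  cycle * spec$period + spec$systole_fraction * spec$period / 2
}

# dimensionless systolic shape s(t) in [0, 1]: sin^2 bump over the systolic
# window, zero in diastole; periodic with the cardiac period
.waveform_shape <- function(spec, t) {
  phase <- t %% spec$period
  ts <- spec$systole_fraction * spec$period
  ifelse(phase < ts, sin(pi * phase / ts)^2, 0)
}

#' Inlet velocity at arbitrary times (closed form)
#' @param spec A \code{\link{waveform_spec}}.
#' @param t Times, s.
#' @return Velocity, m/s.
#' @export
waveform_velocity <- function(spec, t) {
  v0 <- spec$diastolic_velocity_fraction * spec$peak_velocity
  v0 + (spec$peak_velocity - v0) * .waveform_shape(spec, t)
}

#' Outlet pressure at arbitrary times (closed form)
#' @inheritParams waveform_velocity
#' @return Pressure, Pa.
#' @export
waveform_pressure <- function(spec, t) {
  spec$outlet_pressure_min +
    (spec$outlet_pressure_max - spec$outlet_pressure_min) * .waveform_shape(spec, t)
}

#' Sample the cardiac waveform
#'
#' @param spec A \code{\link{waveform_spec}}.
#' @param n_cycles Number of cardiac cycles to sample.
#' @return A data frame with columns \code{time_s},
#'   \code{inlet_velocity_mps}, \code{outlet_pressure_pa}, sampled at
#'   \code{n_samples_per_cycle} uniformly spaced times per cycle.
#' @export
generate_waveform <- function(spec, n_cycles = 1) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  n <- spec$n_samples_per_cycle * n_cycles
  t <- (seq_len(n) - 1) * spec$period / spec$n_samples_per_cycle
  data.frame(time_s = t,
             inlet_velocity_mps = waveform_velocity(spec, t),
             outlet_pressure_pa = waveform_pressure(spec, t))
}

#' Flow-stimulus specification
#'
#' Trapezoidal flow pulse delivered by the deformation catheter against the
#' aneurysm wall: zero before \code{onset_time}, linear ramps of
#' \code{ramp_time} up to the plateau \code{flow_rate} and back down after
#' \code{onset_time + duration}. The time integral of the pulse equals
#' \code{flow_rate * duration} exactly (symmetric ramps).
#'
#' @param flow_rate Plateau flow rate, ml/min (protocol levels: 150, 170,
#'   190).
#' @param duration Plateau-holding duration, s.
#' @param onset_time Pulse trigger time, s.
#' @param ramp_time Linear ramp duration, s.
#' @return An object of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(flow_rate = 170, duration = 3,
                          onset_time = 0, ramp_time = 0.05) {
  if (flow_rate <= 0) stop("flow_rate must be > 0 ml/min")
  if (duration <= 0) stop("duration must be > 0 s")
  if (ramp_time < 0 || ramp_time >= duration)
    stop("ramp_time must be >= 0 and < duration")
  structure(list(flow_rate = flow_rate, duration = duration,
                 onset_time = onset_time, ramp_time = ramp_time),
            class = "stimulus_spec")
}

#' Stimulus flow rate at arbitrary times (closed form)
#' @param spec A \code{\link{stimulus_spec}}.
#' @param t Times, s.
#' @return Flow rate, ml/min.
#' @export
stimulus_flow <- function(spec, t) {
  u <- t - spec$onset_time
  r <- spec$ramp_time
  d <- spec$duration
  up <- if (r > 0) pmin(pmax(u / r, 0), 1) else as.numeric(u >= 0)
  dn <- if (r > 0) pmin(pmax((d + r - u) / r, 0), 1) else as.numeric(u <= d)
  spec$flow_rate * pmin(up, dn)
}

#' Sample the flow stimulus
#'
#' @param spec A \code{\link{stimulus_spec}}.
#' @param times Sample times, s; default spans the pulse at 1 ms.
#' @return Data frame with columns \code{time_s}, \code{stimulus_mlmin}.
#' @export
generate_stimulus <- function(spec, times = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (is.null(times)) {
    t_end <- spec$onset_time + spec$duration + 2 * spec$ramp_time
    times <- seq(min(0, spec$onset_time), t_end, by = 0.001)
  }
  data.frame(time_s = times, stimulus_mlmin = stimulus_flow(spec, times))
}

#' Hemodynamic + stimulus load program
#'
#' Bundles the periodic cardiac waveform, the catheter flow pulse and the
#' catheter geometry into the time-resolved loading consumed by the forward
#' model. All series share one uniform time grid.
#'
#' @param waveform A \code{\link{waveform_spec}}.
#' @param stimulus A \code{\link{stimulus_spec}}, or \code{NULL} for a
#'   stimulus-free (baseline) program.
#' @param t_end End of the time grid, s; defaults to one cardiac cycle past
#'   the end of the stimulus pulse (or two cycles if no stimulus).
#' @param dt Grid step, s.
#' @param catheter_inner_diameter,catheter_outer_diameter Catheter lumen and
#'   outer diameters, mm (5 Fr device: 1.68 / 1.87 mm).
#' @return An object of class \code{load_program} with element
#'   \code{series}, a data frame (\code{time_s}, \code{inlet_velocity_mps},
#'   \code{outlet_pressure_pa}, \code{stimulus_mlmin}).
#' @export
load_program <- function(waveform, stimulus = NULL, t_end = NULL, dt = 0.001,
                         catheter_inner_diameter = 1.68,
                         catheter_outer_diameter = 1.87) {
  stopifnot(inherits(waveform, "waveform_spec"))
  if (!is.null(stimulus)) stopifnot(inherits(stimulus, "stimulus_spec"))
  if (catheter_inner_diameter <= 0 || catheter_outer_diameter <= 0)
    stop("catheter diameters must be > 0 mm")
  if (catheter_outer_diameter < catheter_inner_diameter)
    stop("catheter outer diameter must be >= inner diameter")
  if (is.null(t_end)) {
    t_end <- if (is.null(stimulus)) 2 * waveform$period
             else stimulus$onset_time + stimulus$duration +
                  2 * stimulus$ramp_time + waveform$period
  }
  t <- seq(0, t_end, by = dt)
  q <- if (is.null(stimulus)) rep(0, length(t)) else stimulus_flow(stimulus, t)
  structure(list(
    waveform = waveform,
    stimulus = stimulus,
    series = data.frame(time_s = t,
                        inlet_velocity_mps = waveform_velocity(waveform, t),
                        outlet_pressure_pa = waveform_pressure(waveform, t),
                        stimulus_mlmin = q),
    catheter_inner_diameter = catheter_inner_diameter,
    catheter_outer_diameter = catheter_outer_diameter
  ), class = "load_program")
}

#' Write a load program's series as CSV
#' @param load A \code{\link{load_program}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_load_program <- function(load, path) {
  stopifnot(inherits(load, "load_program"))
  utils::write.csv(load$series, path, row.names = FALSE)
  invisible(path)
}
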