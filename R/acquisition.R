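# Acquisition schedule, breathing waveforms and sequence-synchronized
# ("timed") motion.

#' CEST acquisition protocol
#'
#' Default values reproduce the clinical protocol the package emulates:
#' 80 saturation offsets uniformly spanning +/-5.00 ppm, a normalization
#' reference at 300 ppm, 3 averages, a pulsed saturation module of 15 pulses
#' of 100 ms with 100 ms inter-pulse delay, a 0.7 s readout, and dual echoes
#' at nominal 2.5/3.7 ms. The inter-echo fat phase is mapped to exact
#' opposed-phase (echo 1) / in-phase (echo 2) so two-point Dixon separation
#' is well-posed; the nominal echo times are metadata.
#'
#' @param n_offsets Number of saturation offsets (default 80).
#' @param max_offset_ppm Half-range of the offset sweep (default 5.00 ppm).
#' @param reference_ppm Offset of the normalization reference (default 300).
#' @param averages Number of averages (default 3).
#' @param n_pulses,t_pulse_s,t_interpulse_s Saturation module: number of
#'   pulses, pulse duration and inter-pulse delay in seconds.
#' @param t_readout_s Image readout duration in seconds (default 0.7).
#' @param echo_times_ms Nominal dual echo times, ms.
#' @param noise_sd Additive Gaussian noise scale on each echo image, relative
#'   to the maximum unsaturated signal.
#' @param offset_order `"descending"` (default, +5 to -5 ppm) or
#'   `"ascending"`.
#' @param interleave `"sweeps"` (default): averages realized as consecutive
#'   full sweeps, each preceded by one reference frame; `"repeats"`:
#'   references first, then each offset acquired `averages` times
#'   back-to-back.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(n_offsets = 80L,
                                 max_offset_ppm = 5.0,
                                 reference_ppm = 300.0,
                                 averages = 3L,
                                 n_pulses = 15L,
                                 t_pulse_s = 0.100,
                                 t_interpulse_s = 0.100,
                                 t_readout_s = 0.7,
                                 echo_times_ms = c(2.5, 3.7),
                                 noise_sd = 0.01,
                                 offset_order = c("descending", "ascending"),
                                 interleave = c("sweeps", "repeats")) {
  offset_order <- match.arg(offset_order)
  interleave <- match.arg(interleave)
  stopifnot(n_offsets >= 1L, max_offset_ppm > 0, averages >= 1L,
            n_pulses >= 1L, t_pulse_s > 0, t_interpulse_s > 0, t_readout_s > 0,
            noise_sd >= 0)
  if (abs(reference_ppm) <= max_offset_ppm) {
    stop("reference offset must lie outside the sampled +/- range")
  }
  offsets <- seq(max_offset_ppm, -max_offset_ppm, length.out = n_offsets)
  if (offset_order == "ascending") offsets <- rev(offsets)
  structure(
    list(offsets_ppm = offsets, reference_ppm = reference_ppm,
         averages = as.integer(averages), n_pulses = as.integer(n_pulses),
         t_pulse_s = t_pulse_s, t_interpulse_s = t_interpulse_s,
         t_readout_s = t_readout_s, echo_times_ms = echo_times_ms,
         noise_sd = noise_sd, offset_order = offset_order,
         interleave = interleave),
    class = "acquisition_protocol"
  )
}

#' Frame period of the protocol
#'
#' The saturation module lasts `n_pulses * t_pulse + (n_pulses - 1) *
#' t_interpulse` (no trailing inter-pulse gap); the frame period adds the
#' readout. With the default protocol this gives 2.9 s saturation + 0.7 s
#' readout = 3.6 s per image, i.e. ~16.7 images per minute.
#'
#' @param protocol An [acquisition_protocol()].
#' @return List with `saturation_s`, `readout_s`, `total_s`.
#' @export
frame_period <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  sat <- protocol$n_pulses * protocol$t_pulse_s +
    (protocol$n_pulses - 1L) * protocol$t_interpulse_s
  list(saturation_s = sat, readout_s = protocol$t_readout_s,
       total_s = sat + protocol$t_readout_s)
}

#' Frame schedule of a protocol
#'
#' Expands the protocol into the ordered sequence of acquired frames with
#' saturation-start and readout-midpoint times. The readout is treated as
#' instantaneous at the midpoint of its window.
#'
#' @param protocol An [acquisition_protocol()].
#' @return `data.frame` with one row per frame: `frame`, `offset_ppm`,
#'   `is_reference`, `average`, `sat_start_s`, `readout_mid_s`.
#' @export
acquisition_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  fp <- frame_period(protocol)
  if (protocol$interleave == "sweeps") {
    offs <- rep(c(protocol$reference_ppm, protocol$offsets_ppm),
                times = protocol$averages)
    avg <- rep(seq_len(protocol$averages),
               each = length(protocol$offsets_ppm) + 1L)
  } else {
    offs <- c(rep(protocol$reference_ppm, protocol$averages),
              rep(protocol$offsets_ppm, each = protocol$averages))
    avg <- c(seq_len(protocol$averages),
             rep(seq_len(protocol$averages), length(protocol$offsets_ppm)))
  }
  n <- length(offs)
  sat_start <- (seq_len(n) - 1L) * fp$total_s
  data.frame(
    frame = seq_len(n),
    offset_ppm = offs,
    is_reference = offs == protocol$reference_ppm,
    average = avg,
    sat_start_s = sat_start,
    readout_mid_s = sat_start + fp$saturation_s + fp$readout_s / 2
  )
}

#' Breathing / motion model
#'
#' Parameterizes the rigid superior-inferior translation of the phantom.
#' In periodic mode the waveform is a trapezoid with period `60 / rate_bpm`:
#' an exhale dwell at 0 mm (2/3 of the period by default), a linear ramp at
#' `velocity_mm_s`, an inhale dwell at `amplitude_mm` (1/3 of the period),
#' and a ramp back; the ramps are carved from the ends of the dwells, so
#' displacement is exactly 0 / `amplitude_mm` on the plateaus. In timed
#' mode one full motion cycle (ramp - `hold_s` at amplitude - ramp) is
#' triggered at each saturation onset, see [timed_motion()].
#'
#' @param mode `"static"`, `"periodic"` or `"timed"`.
#' @param rate_bpm Breathing rate in breaths per minute (periodic mode).
#' @param amplitude_mm Peak displacement, mm (default 10).
#' @param inhale_dwell_frac,exhale_dwell_frac Fractions of the breath period
#'   spent inhaled / exhaled; must sum to 1 (defaults 1/3 and 2/3).
#' @param velocity_mm_s Translation speed during ramps, mm/s (default 100,
#'   i.e. ~10 cm/s).
#' @param phase_s Waveform time origin in seconds; `NULL` (default) aligns
#'   the start of the exhale plateau with the first readout midpoint when the
#'   model is used in [simulate_series()].
#' @param hold_s Timed mode: dwell at amplitude per triggered cycle, s.
#' @param jitter_s Timed mode: SD of Gaussian trigger-timing jitter, s.
#' @param seed Integer seed for the optional timing jitter.
#' @return An object of class `breathing_model`.
#' @export
breathing_model <- function(mode = c("static", "periodic", "timed"),
                            rate_bpm = 12,
                            amplitude_mm = 10,
                            inhale_dwell_frac = 1 / 3,
                            exhale_dwell_frac = 2 / 3,
                            velocity_mm_s = 100,
                            phase_s = NULL,
                            hold_s = 1.0,
                            jitter_s = 0,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(amplitude_mm >= 0, velocity_mm_s > 0, hold_s > 0, jitter_s >= 0)
  if (abs(inhale_dwell_frac + exhale_dwell_frac - 1) > 1e-9) {
    stop("dwell fractions must sum to 1")
  }
  if (mode == "periodic") {
    stopifnot(rate_bpm > 0)
    period <- 60 / rate_bpm
    trans <- amplitude_mm / velocity_mm_s
    if (trans >= inhale_dwell_frac * period ||
        trans >= exhale_dwell_frac * period) {
      stop("transition time amplitude/velocity must be shorter than each dwell time")
    }
  }
  structure(
    list(mode = mode, rate_bpm = rate_bpm, amplitude_mm = amplitude_mm,
         inhale_dwell_frac = inhale_dwell_frac,
         exhale_dwell_frac = exhale_dwell_frac,
         velocity_mm_s = velocity_mm_s, phase_s = phase_s,
         hold_s = hold_s, jitter_s = jitter_s, seed = as.integer(seed)),
    class = "breathing_model"
  )
}

#' Displacement of the breathing waveform at time t
#'
#' @param model A [breathing_model()] in static or periodic mode (timed mode
#'   requires the frame schedule, see [timed_motion()]).
#' @param t Time(s) in seconds, >= 0 relative to scan start. Vectorized.
#' @return Displacement(s) in mm; 0 is the exhaled position.
#' @export
displacement <- function(model, t) {
  stopifnot(inherits(model, "breathing_model"))
  if (model$mode == "static") return(rep(0, length(t)))
  if (model$mode == "timed") {
    stop("timed mode is driven by the frame schedule; use timed_motion()")
  }
  period <- 60 / model$rate_bpm
  phase <- if (is.null(model$phase_s)) 0 else model$phase_s
  u <- (t - phase) %% period
  A <- model$amplitude_mm
  tau <- A / model$velocity_mm_s
  E <- model$exhale_dwell_frac * period
  I <- model$inhale_dwell_frac * period
  d <- numeric(length(u))
  ramp_up <- u >= (E - tau) & u < E
  d[ramp_up] <- (u[ramp_up] - (E - tau)) * model$velocity_mm_s
  plateau <- u >= E & u < (E + I - tau)
  d[plateau] <- A
  ramp_dn <- u >= (E + I - tau)
  d[ramp_dn] <- A - (u[ramp_dn] - (E + I - tau)) * model$velocity_mm_s
  pmin(pmax(d, 0), A)
}

#' Sequence-synchronized (timed) motion waveform
#'
#' Models the sound-triggered phantom drive: exactly one full motion cycle
#' (0 -> amplitude -> 0) is initiated at each frame's saturation onset and
#' completes inside the saturation window, so displacement at every readout
#' midpoint is 0.
#'
#' @param sched Frame schedule from [acquisition_schedule()].
#' @param model A [breathing_model()] with `mode = "timed"`.
#' @param protocol The [acquisition_protocol()] that produced `sched`.
#' @return A vectorized function `f(t)` returning displacement in mm.
#' @export
timed_motion <- function(sched, model, protocol) {
  stopifnot(inherits(model, "breathing_model"), model$mode == "timed")
  fp <- frame_period(protocol)
  A <- model$amplitude_mm
  tau <- A / model$velocity_mm_s
  cycle <- 2 * tau + model$hold_s
  jit <- rep(0, nrow(sched))
  if (model$jitter_s > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(model$seed)
    jit <- abs(stats::rnorm(nrow(sched), sd = model$jitter_s))
  }
  if (any(cycle + jit > fp$saturation_s)) {
    stop("timed motion cycle (2*amplitude/velocity + hold) does not fit in the saturation window")
  }
  starts <- sched$sat_start_s + jit
  total <- fp$total_s
  function(t) {
    if (A == 0) return(rep(0, length(t)))
    k <- pmin(pmax(floor(t / total) + 1, 1), nrow(sched))
    u <- t - starts[k]
    d <- numeric(length(u))
    up <- u >= 0 & u < tau
    d[up] <- u[up] * model$velocity_mm_s
    hold <- u >= tau & u < tau + model$hold_s
    d[hold] <- A
    dn <- u >= tau + model$hold_s & u < cycle
    d[dn] <- A - (u[dn] - tau - model$hold_s) * model$velocity_mm_s
    pmin(pmax(d, 0), A)
  }
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a respiratory-cushion log
#'
#' Samples a displacement-proxy channel from a breathing waveform, optionally
#' with additive sensor noise, as recorded by a pneumatic breathing cushion.
#'
#' @param waveform Either a [breathing_model()] (static/periodic) or a
#'   function of time returning displacement in mm (e.g. from
#'   [timed_motion()]).
#' @param duration_s Length of the recording in seconds.
#' @param sample_rate_hz Sampling frequency (default 50 Hz).
#' @param tags Acquisition time tags (readout midpoints), seconds; must lie
#'   inside the sampled interval.
#' @param noise_sd Additive Gaussian sensor noise, in the same arbitrary
#'   units as the signal.
#' @param seed Integer seed for the sensor noise.
#' @return An object of class `cushion_log`: list with `time`, `value`,
#'   `sample_rate_hz`, `tags`.
#' @export
cushion_log <- function(waveform, duration_s, sample_rate_hz = 50,
                        tags = numeric(0), noise_sd = 0, seed = 1L) {
  stopifnot(duration_s > 0, sample_rate_hz > 0)
  f <- if (inherits(waveform, "breathing_model")) {
    function(t) displacement(waveform, t)
  } else {
    stopifnot(is.function(waveform))
    waveform
  }
  time <- seq(0, duration_s, by = 1 / sample_rate_hz)
  value <- f(time)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    value <- value + stats::rnorm(length(value), sd = noise_sd)
  }
  if (length(tags) && (min(tags) < 0 || max(tags) > duration_s)) {
    stop("acquisition tags must lie inside the sampled interval")
  }
  structure(
    list(time = time, value = value, sample_rate_hz = sample_rate_hz,
         tags = tags),
    class = "cushion_log"
  )
}

#' Write / read a cushion log as plain text
#'
#' Two-column whitespace-separated `(time_s, value)` samples plus a sidecar
#' `<path>.tags` file holding the acquisition time tags, one per line.
#'
#' @param log A `cushion_log`.
#' @param path Output file path for the samples.
#' @export
write_cushion_log <- function(log, path) {
  stopifnot(inherits(log, "cushion_log"))
  utils::write.table(
    data.frame(time_s = log$time, value = log$value),
    path, row.names = FALSE, quote = FALSE
  )
  writeLines(format(log$tags, digits = 12), paste0(path, ".tags"))
  invisible(path)
}

#' @rdname write_cushion_log
#' @export
read_cushion_log <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  tags <- as.numeric(readLines(paste0(path, ".tags")))
  dt <- diff(df$time_s)
  structure(
    list(time = df$time_s, value = df$value,
         sample_rate_hz = 1 / stats::median(dt), tags = tags),
    class = "cushion_log"
  )
}
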