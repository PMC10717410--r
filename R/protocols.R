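#' Current-clamp stimulation protocol
#'
#' A holding current plus rectangular pulses. During a pulse the commanded
#' amplifier current equals the pulse `amplitude` (it replaces, not adds to,
#' the holding current), matching how a command step is delivered in
#' current clamp. Negative amplitudes depolarize (see [membrane_rhs()]).
#'
#' @param i_hold Holding current (pA) outside pulses.
#' @param pulses Data frame with columns `onset`, `duration`, `amplitude`
#'   (ms, ms, pA); may be empty. Pulses must lie within
#'   `[0, total_time]` and not overlap.
#' @param total_time Protocol duration (ms).
#' @param sample_dt Output sampling interval (ms).
#' @return An object of class `cc_protocol`.
#' @export
current_clamp_protocol <- function(i_hold = 10,
                                   pulses = data.frame(onset = numeric(),
                                                       duration = numeric(),
                                                       amplitude = numeric()),
                                   total_time = 1000, sample_dt = 0.01) {
  stopifnot(is.data.frame(pulses),
            all(c("onset", "duration", "amplitude") %in% names(pulses)))
  if (sample_dt <= 0) stop("sample_dt must be > 0", call. = FALSE)
  if (nrow(pulses) > 0) {
    pulses <- pulses[order(pulses$onset), , drop = FALSE]
    if (any(pulses$onset < 0) ||
        any(pulses$onset + pulses$duration > total_time)) {
      stop("pulses must lie within [0, total_time]", call. = FALSE)
    }
    ends <- pulses$onset + pulses$duration
    if (nrow(pulses) > 1 && any(pulses$onset[-1] < ends[-nrow(pulses)])) {
      stop("pulses must not overlap", call. = FALSE)
    }
  }
  structure(list(i_hold = i_hold, pulses = pulses, total_time = total_time,
                 sample_dt = sample_dt), class = "cc_protocol")
}

#' Stimulation protocols of the firing simulations
#'
#' `protocol_brief_pulses()` delivers brief strong depolarizing pulses at a
#' fixed rate (default: -140 pA for 1 ms at 2 Hz on a +10 pA hold), the
#' single-action-potential protocol. `protocol_current_step()` delivers one
#' long step (default: -15 pA for 500 ms), the spike-train protocol.
#'
#' @param n_pulses Number of pulses.
#' @param rate_hz Pulse rate (Hz).
#' @param amplitude Commanded current during the pulse/step (pA).
#' @param width Pulse width (ms).
#' @param i_hold Holding current (pA).
#' @param first_onset Onset of the first pulse (ms).
#' @param sample_dt Output sampling interval (ms).
#' @return A `cc_protocol`.
#' @export
protocol_brief_pulses <- function(n_pulses = 4, rate_hz = 2,
                                  amplitude = -140, width = 1,
                                  i_hold = 10, first_onset = 50,
                                  sample_dt = 0.01) {
  period <- 1000 / rate_hz
  onsets <- first_onset + period * (seq_len(n_pulses) - 1)
  current_clamp_protocol(
    i_hold = i_hold,
    pulses = data.frame(onset = onsets, duration = width,
                        amplitude = amplitude),
    total_time = n_pulses * period,
    sample_dt = sample_dt)
}

#' @rdname protocol_brief_pulses
#' @param duration Step duration (ms).
#' @param onset Step onset (ms).
#' @param tail Post-step settle time (ms).
#' @export
protocol_current_step <- function(amplitude = -15, duration = 500,
                                  i_hold = 10, onset = 50, tail = 50,
                                  sample_dt = 0.01) {
  current_clamp_protocol(
    i_hold = i_hold,
    pulses = data.frame(onset = onset, duration = duration,
                        amplitude = amplitude),
    total_time = onset + duration + tail,
    sample_dt = sample_dt)
}

#' Voltage-clamp protocol
#'
#' Families of step pulses or a single ramp, as in the whole-cell
#' recordings: 10 mV steps of 400 ms from -100 to +100 mV, or a ramp from
#' -100 to +100 mV over 300 ms, from a -60 mV holding potential.
#'
#' @param v_hold Holding potential (mV).
#' @param mode `"steps"` or `"ramp"`.
#' @param step_from,step_to,step_increment Step family limits and increment
#'   (mV); `step_increment > 0`.
#' @param step_duration Step duration (ms).
#' @param ramp_from,ramp_to Ramp limits (mV).
#' @param ramp_duration Ramp duration (ms).
#' @param inter_sweep Interval between sweep onsets (ms); bookkeeping only.
#' @param sample_dt Output sampling interval (ms).
#' @return An object of class `vc_protocol`.
#' @export
voltage_clamp_protocol <- function(v_hold = -60,
                                   mode = c("steps", "ramp"),
                                   step_from = -100, step_to = 100,
                                   step_increment = 10,
                                   step_duration = 400,
                                   ramp_from = -100, ramp_to = 100,
                                   ramp_duration = 300,
                                   inter_sweep = 5000,
                                   sample_dt = 1) {
  mode <- match.arg(mode)
  if (mode == "steps" && step_increment <= 0) {
    stop("step_increment must be > 0", call. = FALSE)
  }
  if (sample_dt <= 0) stop("sample_dt must be > 0", call. = FALSE)
  structure(list(v_hold = v_hold, mode = mode, step_from = step_from,
                 step_to = step_to, step_increment = step_increment,
                 step_duration = step_duration, ramp_from = ramp_from,
                 ramp_to = ramp_to, ramp_duration = ramp_duration,
                 inter_sweep = inter_sweep, sample_dt = sample_dt),
            class = "vc_protocol")
}
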