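# deSolve-facing right-hand side: state y = (v, m, h, n, a).
.ode_rhs <- function(t, y, parms) {
  list(membrane_rhs(y, t, parms$params, parms$i_app))
}

# Integrate one constant-current segment on the sample grid. `y0` is the
# state at `t0`; returns the matrix of states at the requested grid times
# (exclusive of t0 unless it is a grid point already handled by the caller).
integrate_segment <- function(params, i_app, t0, t1, grid, y0,
                              rtol, atol, hmax) {
  times <- sort(unique(c(t0, grid[grid > t0 & grid <= t1], t1)))
  if (length(times) < 2) times <- c(t0, t1)
  out <- deSolve::lsoda(y = y0, times = times, func = .ode_rhs,
                        parms = list(params = params, i_app = i_app),
                        rtol = rtol, atol = atol, hmax = hmax)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed in segment [", t0, ", ", t1, "] ms",
         call. = FALSE)
  }
  out
}

#' Simulate a current-clamp protocol
#'
#' Integrates the membrane equation through the holding/pulse segments of a
#' [current_clamp_protocol()] with a stiff-capable adaptive solver
#' (`deSolve::lsoda`), restarting at every current discontinuity so no pulse
#' can be stepped over. The integration is deterministic: identical inputs
#' give bitwise-identical traces. Gates start at their steady state for the
#' holding current unless an explicit initial state is supplied.
#'
#' @param params A [cell_params()] object (typically calibrated, see
#'   [calibrate_cell()]).
#' @param protocol A [current_clamp_protocol()].
#' @param init Optional initial state `c(v, m, h, n, a)`; default
#'   `steady_state(params, protocol$i_hold)`.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param hmax_pulse Maximum internal step (ms) during pulse segments.
#' @return A voltage [new_trace()] sampled every `protocol$sample_dt` ms.
#' @export
simulate_current_clamp <- function(params, protocol, init = NULL,
                                   rtol = 1e-8, atol = 1e-10,
                                   hmax_pulse = 0.05) {
  stopifnot(inherits(params, "cell_params"),
            inherits(protocol, "cc_protocol"))
  grid <- seq(0, protocol$total_time, by = protocol$sample_dt)
  y0 <- if (is.null(init)) steady_state(params, protocol$i_hold) else init
  # Build the (t0, t1, i_app, is_pulse) segment table.
  p <- protocol$pulses
  bounds <- sort(unique(c(0, p$onset, p$onset + p$duration,
                          protocol$total_time)))
  seg_i <- vapply(seq_len(length(bounds) - 1), function(k) {
    mid <- (bounds[k] + bounds[k + 1]) / 2
    hit <- which(p$onset <= mid & mid < p$onset + p$duration)
    if (length(hit)) p$amplitude[hit[1]] else protocol$i_hold
  }, numeric(1))
  vals <- numeric(length(grid)); vals[1] <- y0[["v"]]
  states <- matrix(NA_real_, nrow = length(grid), ncol = 5)
  states[1, ] <- y0
  y <- y0
  for (k in seq_along(seg_i)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    is_pulse <- seg_i[k] != protocol$i_hold
    out <- integrate_segment(params, seg_i[k], t0, t1, grid, y,
                             rtol, atol,
                             hmax = if (is_pulse) hmax_pulse else Inf)
    tt <- out[, 1]
    on_grid <- which(tt %in% grid & tt > t0 + 1e-12)
    idx <- match(round(tt[on_grid] / protocol$sample_dt),
                 round(grid / protocol$sample_dt))
    states[idx, ] <- out[on_grid, -1, drop = FALSE]
    y <- out[nrow(out), -1]
    names(y) <- c("v", "m", "h", "n", "a")
  }
  new_trace(grid, states[, 1], kind = "voltage",
            metadata = list(protocol = unclass(protocol)[
              c("i_hold", "total_time", "sample_dt")],
              pulses = protocol$pulses,
              tmc4_scale = params$tmc4$scale_factor,
              cm = params$cm))
}

# Closed-form first-order gate relaxation at a fixed clamped voltage.
relax_gate <- function(t, x0, x_inf, tau) {
  x_inf + (x0 - x_inf) * exp(-t / tau)
}

#' Simulate a voltage-clamp protocol
#'
#' Computes the ionic (non-capacitive) clamp current. Under a voltage step
#' the gate ODEs are linear with constant coefficients, so gates relax in
#' closed form and the current is evaluated exactly on the sample grid; for
#' a ramp the gate equations are integrated numerically along the commanded
#' voltage. The capacitive transient is excluded by construction because
#' only ionic current is reported.
#'
#' @param params A [cell_params()] object.
#' @param protocol A [voltage_clamp_protocol()].
#' @return A [sweep_set()] with one current trace per step (21 sweeps for
#'   -100..+100 by 10), or a single ramp trace.
#' @export
simulate_voltage_clamp <- function(params, protocol) {
  stopifnot(inherits(params, "cell_params"),
            inherits(protocol, "vc_protocol"))
  y_hold <- cell_gate_ss(protocol$v_hold, params)
  if (protocol$mode == "steps") {
    steps <- seq(protocol$step_from, protocol$step_to,
                 by = protocol$step_increment)
    grid <- seq(0, protocol$step_duration, by = protocol$sample_dt)
    traces <- lapply(steps, function(vs) {
      m <- relax_gate(grid, y_hold[["m"]],
                      gate_steady_state(vs, params$m_gate),
                      gate_tau(vs, params$m_gate))
      h <- relax_gate(grid, y_hold[["h"]],
                      gate_steady_state(vs, params$h_gate),
                      gate_tau(vs, params$h_gate))
      n <- relax_gate(grid, y_hold[["n"]],
                      gate_steady_state(vs, params$n_gate),
                      gate_tau(vs, params$n_gate))
      a_inf <- tmc4_activation(vs, params$tmc4)
      a <- if (params$tmc4$tau_act > 0) {
        relax_gate(grid, y_hold[["a"]], a_inf, params$tmc4$tau_act)
      } else rep(a_inf, length(grid))
      i <- total_ionic_current(vs, m, h, n, a, params)
      new_trace(grid, i, kind = "current",
                metadata = list(step_mV = vs, v_hold = protocol$v_hold))
    })
    sweep_set(traces, steps)
  } else {
    grid <- seq(0, protocol$ramp_duration, by = protocol$sample_dt)
    slope <- (protocol$ramp_to - protocol$ramp_from) / protocol$ramp_duration
    v_of_t <- function(t) protocol$ramp_from + slope * t
    gate_rhs <- function(t, y, parms) {
      v <- v_of_t(t)
      da <- if (params$tmc4$tau_act > 0) {
        (tmc4_activation(v, params$tmc4) - y[4]) / params$tmc4$tau_act
      } else 0
      list(c(gate_derivative(y[1], v, params$m_gate),
             gate_derivative(y[2], v, params$h_gate),
             gate_derivative(y[3], v, params$n_gate),
             da))
    }
    out <- deSolve::lsoda(y = unname(y_hold), times = grid, func = gate_rhs,
                          parms = NULL, rtol = 1e-8, atol = 1e-10)
    v <- v_of_t(grid)
    a <- if (params$tmc4$tau_act > 0) out[, 5] else
      tmc4_activation(v, params$tmc4)
    i <- total_ionic_current(v, out[, 2], out[, 3], out[, 4], a, params)
    tr <- new_trace(grid, i, kind = "current",
                    metadata = list(mode = "ramp",
                                    ramp_mV = c(protocol$ramp_from,
                                                protocol$ramp_to)))
    sweep_set(list(tr), NA_real_)
  }
}

#' Sweep the TMC4 conductance-amplification factor
#'
#' Repeats a current-clamp simulation with `tmc4$scale_factor` set to each
#' requested multiplier (the "expression level" axis of the firing
#' simulations), everything else identical.
#'
#' @param params A [cell_params()] object.
#' @param factors Non-negative multipliers, e.g. `seq(0, 3, by = 0.5)`.
#' @param protocol A [current_clamp_protocol()].
#' @param ... Passed to [simulate_current_clamp()].
#' @return Named list: `factors`, and `traces` (one voltage trace each).
#' @export
conductance_sweep <- function(params, factors, protocol, ...) {
  if (any(factors < 0)) stop("factors must be >= 0", call. = FALSE)
  traces <- lapply(factors, function(f) {
    p <- params
    p$tmc4$scale_factor <- f
    simulate_current_clamp(p, protocol, ...)
  })
  list(factors = factors, traces = traces)
}
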