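#' Hodgkin-Huxley gate parameterisation
#'
#' First-order voltage-dependent gating, `dx/dt = (x_inf(v) - x) / tau(v)`,
#' with a Boltzmann steady state `x_inf(v) = 1 / (1 + exp(-(v - v_half)/k))`
#' and a bell-shaped time constant centred on `v_half`,
#' `tau(v) = tau_min + (tau_max - tau_min) / cosh((v - v_half) / (2|k|))`.
#' A negative `slope_k` describes an inactivation gate (open fraction falls
#' with depolarization).
#'
#' @param v_half Half-activation voltage (mV).
#' @param slope_k Boltzmann slope (mV); non-zero. Negative for inactivation.
#' @param tau_min,tau_max Bounds of the voltage-dependent time constant (ms);
#'   `0 < tau_min <= tau_max`.
#' @param exponent Integer power the gate enters the conductance with
#'   (e.g. 3 for m^3, 4 for n^4).
#' @return An object of class `hh_gate`.
#' @export
hh_gate <- function(v_half, slope_k, tau_min, tau_max, exponent = 1L) {
  if (!is.finite(slope_k) || slope_k == 0) {
    stop("slope_k must be non-zero", call. = FALSE)
  }
  if (!is.finite(tau_min) || !is.finite(tau_max) ||
      tau_min <= 0 || tau_min > tau_max) {
    stop("need 0 < tau_min <= tau_max", call. = FALSE)
  }
  if (exponent < 1 || exponent != round(exponent)) {
    stop("exponent must be a positive integer", call. = FALSE)
  }
  structure(list(v_half = v_half, slope_k = slope_k,
                 tau_min = tau_min, tau_max = tau_max,
                 exponent = as.integer(exponent)),
            class = "hh_gate")
}

boltzmann <- function(v, v_half, slope_k) {
  1 / (1 + exp(-(v - v_half) / slope_k))
}

#' Gate steady state, time constant and derivative
#'
#' @param v Membrane potential (mV); vectorised.
#' @param gate An [hh_gate()] object.
#' @return `gate_steady_state()`: the open fraction `x_inf(v)` in \[0, 1\].
#'   `gate_tau()`: the relaxation time constant (ms), within
#'   `[tau_min, tau_max]`. `gate_derivative()`: `dx/dt` in ms^-1, zero iff
#'   `x == x_inf(v)`.
#' @export
gate_steady_state <- function(v, gate) {
  boltzmann(v, gate$v_half, gate$slope_k)
}

#' @rdname gate_steady_state
#' @export
gate_tau <- function(v, gate) {
  gate$tau_min + (gate$tau_max - gate$tau_min) /
    cosh((v - gate$v_half) / (2 * abs(gate$slope_k)))
}

#' @rdname gate_steady_state
#' @param x Current open fraction of the gate.
#' @export
gate_derivative <- function(x, v, gate) {
  (gate_steady_state(v, gate) - x) / gate_tau(v, gate)
}
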