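#' Whole-cell model parameters
#'
#' Assembles the taste-bud-cell membrane model: capacitance, the classical
#' Na+/K+/leak conductances with their gates, the TMC4 block, and the ionic
#' conditions that fix the Nernst reversals. The membrane equation is
#'
#' `cm * dV/dt = -(I_Na + I_K + I_leak + I_TMC4 + i_app)`
#'
#' with the sign convention that a NEGATIVE applied current depolarizes (a
#' -140 pA stimulus evokes a spike, a +10 pA holding current keeps the cell
#' below rest). Gates follow first-order kinetics towards their Boltzmann
#' steady states.
#'
#' @param cm Membrane capacitance (pF).
#' @param g_na,g_k,g_leak Maximal conductances (nS).
#' @param e_leak Leak reversal potential (mV).
#' @param m_gate,h_gate,n_gate [hh_gate()] parameter blocks for Na+
#'   activation (m^3), Na+ inactivation (h) and delayed-rectifier K+
#'   activation (n^4).
#' @param tmc4 A [tmc4_params()] block.
#' @param conditions An [ionic_conditions()] object.
#' @return An object of class `cell_params`.
#' @seealso [default_cell_params()], [calibrate_cell()], [hek_cell_params()]
#' @export
cell_params <- function(cm = 10,
                        g_na = 120, g_k = 20, g_leak = 2, e_leak = -66,
                        m_gate = hh_gate(-50, 4, 0.02, 0.2, 3L),
                        h_gate = hh_gate(-58, -3, 0.3, 5, 1L),
                        n_gate = hh_gate(-50, 5, 1.5, 4, 4L),
                        tmc4 = tmc4_params(g_max = 30, v_half = 0,
                                           slope_k = 12,
                                           e_rev_mode = "nernst_cl",
                                           tau_act = 1),
                        conditions = ionic_conditions()) {
  if (cm <= 0) stop("cm must be > 0", call. = FALSE)
  if (any(c(g_na, g_k, g_leak) < 0)) {
    stop("conductances must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(tmc4, "tmc4_params"),
            inherits(conditions, "ionic_conditions"),
            inherits(m_gate, "hh_gate"), inherits(h_gate, "hh_gate"),
            inherits(n_gate, "hh_gate"))
  structure(list(cm = cm, g_na = g_na, g_k = g_k, g_leak = g_leak,
                 e_leak = e_leak, m_gate = m_gate, h_gate = h_gate,
                 n_gate = n_gate, tmc4 = tmc4, conditions = conditions,
                 reversals = reversal_set(conditions)),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Taste-cell model parameters\n")
  cat(sprintf("  cm %.3g pF | g_Na %.4g, g_K %.4g, g_leak %.4g nS (E_leak %.2f mV)\n",
              x$cm, x$g_na, x$g_k, x$g_leak, x$e_leak))
  cat(sprintf("  TMC4: g %.3g nS x factor %.3g, V1/2 %g mV, k %g mV, tau_act %g ms (%s)\n",
              x$tmc4$g_max, x$tmc4$scale_factor, x$tmc4$v_half,
              x$tmc4$slope_k, x$tmc4$tau_act, x$tmc4$e_rev_mode))
  print(x$reversals)
  invisible(x)
}

#' Uncalibrated base parameter set
#'
#' The model shape with nominal conductances, before the leak and Na+
#' conductances are pinned down by [calibrate_cell()]. Gating constants are
#' model design choices (documented in the methods vignette), not measured
#' values.
#'
#' @param tmc4_factor TMC4 expression-level multiplier (`scale_factor`).
#' @return A `cell_params` object.
#' @export
default_cell_params <- function(tmc4_factor = 1) {
  p <- cell_params()
  p$tmc4$scale_factor <- tmc4_factor
  p
}

#' Heterologous (HEK-cell) expression configuration
#'
#' A TMC4-only whole-cell configuration mimicking the transfection
#' experiments: no voltage-gated Na+/K+ currents, instantaneous TMC4 gating
#' with the channel-level Boltzmann defaults, and a fixed empirical reversal
#' potential (-27.6 mV for the KCl pipette solution, -25.6 mV for NMDG-Cl).
#'
#' @param pipette `"kcl"` or `"nmdg"`; selects the fixed reversal.
#' @param g_max TMC4 maximal conductance (nS).
#' @return A `cell_params` object with only TMC4 conductance.
#' @export
hek_cell_params <- function(pipette = c("kcl", "nmdg"), g_max = 10) {
  pipette <- match.arg(pipette)
  e_rev <- if (pipette == "kcl") -27.6 else -25.6
  cell_params(g_na = 0, g_k = 0, g_leak = 0, e_leak = -60,
              tmc4 = tmc4_params(g_max = g_max, e_rev_mode = "fixed",
                                 e_rev_fixed = e_rev))
}

# Total ionic current (pA) with explicit gate values; the single algebraic
# definition shared by the ODE right-hand side, the steady-state solver and
# the voltage-clamp oracle.
total_ionic_current <- function(v, m, h, n, a, params) {
  rev <- params$reversals
  nav_current(v, m, h, params$g_na, rev$e_na) +
    kdr_current(v, n, params$g_k, rev$e_k) +
    leak_current(v, params$g_leak, params$e_leak) +
    tmc4_current(v, params$tmc4, e_cl = rev$e_cl, activation = a)
}

# Gate steady states at a voltage, including the TMC4 activation gate.
cell_gate_ss <- function(v, params) {
  c(m = gate_steady_state(v, params$m_gate),
    h = gate_steady_state(v, params$h_gate),
    n = gate_steady_state(v, params$n_gate),
    a = tmc4_activation(v, params$tmc4))
}

# Steady-state total ionic current I_ss(v) (all gates at x_inf(v)).
steady_ionic_current <- function(v, params) {
  vapply(v, function(vi) {
    g <- cell_gate_ss(vi, params)
    total_ionic_current(vi, g[["m"]], g[["h"]], g[["n"]], g[["a"]], params)
  }, numeric(1))
}

#' Membrane equation right-hand side
#'
#' Time derivative of the model state
#' `(v_m, m, h, n, a)`: voltage in mV, Na+ activation/inactivation gates,
#' K+ activation gate, and the TMC4 activation gate. Under the sign
#' convention used throughout, `dV/dt = -(I_ion + i_app) / cm`, so negative
#' applied current depolarizes. When `tmc4$tau_act == 0` the TMC4 gate `a`
#' is slaved to its Boltzmann steady state.
#'
#' @param state Named numeric vector `c(v, m, h, n, a)`.
#' @param t Time (ms); unused (autonomous system), kept for ODE interface.
#' @param params A [cell_params()] object.
#' @param i_app Applied clamp current (pA).
#' @return Named numeric vector of derivatives (mV/ms and ms^-1).
#' @export
membrane_rhs <- function(state, t = 0, params = default_cell_params(),
                         i_app = 0) {
  v <- state[["v"]]
  m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  a <- if (params$tmc4$tau_act > 0) state[["a"]] else
    tmc4_activation(v, params$tmc4)
  i_ion <- total_ionic_current(v, m, h, n, a, params)
  da <- if (params$tmc4$tau_act > 0) {
    (tmc4_activation(v, params$tmc4) - a) / params$tmc4$tau_act
  } else 0
  c(v = -(i_ion + i_app) / params$cm,
    m = gate_derivative(m, v, params$m_gate),
    h = gate_derivative(h, v, params$h_gate),
    n = gate_derivative(n, v, params$n_gate),
    a = da)
}

#' Resting state under a constant applied current
#'
#' Finds the hyperpolarized stable fixed point of the membrane equation,
#' i.e. the most negative root of `I_ss(v) + i_app = 0` with all gates at
#' steady state, by a scan-and-bisect root search over \[-120, -35\] mV.
#'
#' @param params A [cell_params()] object.
#' @param i_app Constant applied current (pA); positive hyperpolarizes.
#' @return Named state vector `c(v, m, h, n, a)` with
#'   `||membrane_rhs|| < 1e-9`.
#' @export
steady_state <- function(params, i_app = 0) {
  f <- function(v) steady_ionic_current(v, params) + i_app
  grid <- seq(-120, -35, by = 0.5)
  fv <- f(grid)
  up <- which(fv[-length(fv)] <= 0 & fv[-1] > 0)
  if (length(up) == 0) {
    stop("no stable resting state found in [-120, -35] mV", call. = FALSE)
  }
  i <- up[1]
  root <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  st <- c(v = root, cell_gate_ss(root, params))
  names(st) <- c("v", "m", "h", "n", "a")
  st
}

#' Holding current for a target membrane potential
#'
#' Root-finds the constant current `i` such that
#' `steady_state(params, i)` rests at `v_target`, bracketing `i` from the
#' steady-state current-voltage relation. In the model's sign convention a
#' positive holding current holds the cell below its resting potential (the
#' +10 pA / -70 mV configuration of the stimulation protocols).
#'
#' @param params A [cell_params()] object.
#' @param v_target Target membrane potential (mV).
#' @param tol Voltage tolerance (mV) on the recovered steady state.
#' @return Holding current (pA).
#' @export
find_holding_current <- function(params, v_target, tol = 0.01) {
  # At a fixed point I_ss(v) = -i, so -I_ss(v_target) brackets the answer.
  i0 <- -steady_ionic_current(v_target, params)
  g <- function(i) steady_state(params, i)[["v"]] - v_target
  half <- 1
  repeat {
    lo <- i0 - half; hi <- i0 + half
    glo <- g(lo); ghi <- g(hi)
    if (sign(glo) != sign(ghi)) break
    half <- 2 * half
    if (half > 1e4) stop("cannot bracket holding current", call. = FALSE)
  }
  i <- stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
  if (abs(g(i)) > tol) {
    stop("holding-current search did not converge", call. = FALSE)
  }
  i
}
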