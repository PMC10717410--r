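# Anion species the TMC4 model accepts; chloride is the reference species
# and always carries amplitude factor 1.
.TMC4_ANIONS <- c("chloride", "bromide", "iodide", "gluconate", "acetate",
                  "methanesulfonate")

#' TMC4 channel parameters
#'
#' TMC4 is modelled as a voltage-dependent, Ca2+-insensitive chloride
#' conductance: a Boltzmann open fraction (optionally relaxing with a
#' first-order time constant `tau_act`) times an ohmic driving force.
#' Outward rectification — large outward currents at positive potentials,
#' very small inward currents at negative ones — emerges from the voltage
#' dependence of the open fraction.
#'
#' The reversal potential is either tied to the chloride Nernst potential
#' (`e_rev_mode = "nernst_cl"`, used by the taste-cell model) or fixed to a
#' measured whole-cell value (`e_rev_mode = "fixed"`; -27.6 mV for the KCl
#' pipette and -25.6 mV for the NMDG-Cl pipette configurations).
#'
#' Pharmacological block is a conductance multiplier `block_factor` in
#' \[0, 1\]; anion substitution scales the amplitude per species via
#' `anion_scale` without moving the reversal.
#'
#' @param g_max Maximal conductance (nS).
#' @param scale_factor Dimensionless expression-level multiplier (>= 0); the
#'   conductance-amplification factor swept from 0 to 3 in the firing
#'   simulations.
#' @param v_half,slope_k Boltzmann activation midpoint (mV) and slope
#'   (mV, > 0).
#' @param e_rev_mode `"nernst_cl"` or `"fixed"`.
#' @param e_rev_fixed Reversal potential (mV) used when `e_rev_mode` is
#'   `"fixed"`.
#' @param anion_scale Named numeric vector of per-species amplitude factors
#'   in (0, 1\]; must contain `chloride = 1`.
#' @param tau_act Activation time constant (ms); 0 means instantaneous
#'   gating.
#' @param block_factor Pharmacological conductance multiplier in \[0, 1\]
#'   (1 = no block).
#' @return An object of class `tmc4_params`.
#' @examples
#' p <- tmc4_params()
#' tmc4_current(60, p, e_cl = -41.3)  # ~ 803 pA with the fixed -27.6 mV E_rev
#' @export
tmc4_params <- function(g_max = 10, scale_factor = 1,
                        v_half = 0, slope_k = 25,
                        e_rev_mode = c("fixed", "nernst_cl"),
                        e_rev_fixed = -27.6,
                        anion_scale = c(chloride = 1),
                        tau_act = 0, block_factor = 1) {
  e_rev_mode <- match.arg(e_rev_mode)
  if (!is.finite(slope_k) || slope_k <= 0) {
    stop("slope_k must be > 0", call. = FALSE)
  }
  if (!is.finite(scale_factor) || scale_factor < 0) {
    stop("scale_factor must be >= 0", call. = FALSE)
  }
  if (!is.finite(block_factor) || block_factor < 0 || block_factor > 1) {
    stop("block_factor must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(tau_act) || tau_act < 0) {
    stop("tau_act must be >= 0 (0 = instantaneous)", call. = FALSE)
  }
  if (is.null(names(anion_scale)) || !"chloride" %in% names(anion_scale) ||
      anion_scale[["chloride"]] != 1) {
    stop("anion_scale must contain chloride = 1", call. = FALSE)
  }
  if (any(anion_scale <= 0) || any(anion_scale > 1)) {
    stop("anion_scale factors must lie in (0, 1]", call. = FALSE)
  }
  structure(list(g_max = g_max, scale_factor = scale_factor,
                 v_half = v_half, slope_k = slope_k,
                 e_rev_mode = e_rev_mode, e_rev_fixed = e_rev_fixed,
                 anion_scale = anion_scale, tau_act = tau_act,
                 block_factor = block_factor),
            class = "tmc4_params")
}

tmc4_reversal <- function(params, e_cl) {
  if (params$e_rev_mode == "nernst_cl") e_cl else params$e_rev_fixed
}

#' TMC4 Boltzmann open fraction
#'
#' `1 / (1 + exp(-(v - v_half)/slope_k))`; strictly increasing in `v` with
#' limits 0 and 1. This is the steady-state (instantaneous) activation; when
#' `tau_act > 0` the dynamic open fraction relaxes towards it first-order.
#'
#' @param v Membrane potential (mV); vectorised.
#' @param params A [tmc4_params()] object.
#' @return Open fraction in \[0, 1\].
#' @export
tmc4_activation <- function(v, params = tmc4_params()) {
  stopifnot(inherits(params, "tmc4_params"))
  boltzmann(v, params$v_half, params$slope_k)
}

#' TMC4 chloride current
#'
#' `I = g_max * scale_factor * block_factor * anion_scale[species] *
#' a(v) * (v - E_rev)` in pA. The current is by contract independent of
#' intracellular Ca2+: `ca_i` is accepted only for interface symmetry with
#' the Ca2+-activated comparator [ano1_current()] and never enters the
#' computation.
#'
#' @inheritParams tmc4_activation
#' @param e_cl Chloride Nernst potential (mV); used when
#'   `e_rev_mode = "nernst_cl"`.
#' @param ca_i Intracellular Ca2+ (nM); ignored (Ca2+-insensitivity).
#' @param anion Anion species key; one of the names in
#'   `params$anion_scale`.
#' @param activation Optional dynamic open fraction (overrides the
#'   steady-state Boltzmann; used by the ODE integrator when `tau_act > 0`).
#' @return Current in pA (positive = outward).
#' @export
tmc4_current <- function(v, params = tmc4_params(), e_cl = -41.35,
                         ca_i = NULL, anion = "chloride",
                         activation = NULL) {
  stopifnot(inherits(params, "tmc4_params"))
  if (!anion %in% names(params$anion_scale)) {
    stop("unknown anion species: ", anion, call. = FALSE)
  }
  a <- if (is.null(activation)) tmc4_activation(v, params) else activation
  params$g_max * params$scale_factor * params$block_factor *
    params$anion_scale[[anion]] * a * (v - tmc4_reversal(params, e_cl))
}

#' Ca2+-activated chloride channel (ANO1) comparator
#'
#' A Hill-type Ca2+-gated chloride conductance,
#' `I = g_max * ca^n / (ca^n + ca_half^n) * (v - e_rev)`, used as the
#' Ca2+-sensitive contrast to TMC4: its current increases monotonically with
#' intracellular Ca2+ while TMC4's does not change at all.
#'
#' @param g_max Maximal conductance (nS).
#' @param ca_half Half-activating Ca2+ concentration (nM, > 0).
#' @param hill_n Hill coefficient (> 0).
#' @param e_rev Reversal potential (mV).
#' @return An object of class `ano1_params`.
#' @export
ano1_params <- function(g_max = 10, ca_half = 400, hill_n = 2,
                        e_rev = -27.6) {
  if (ca_half <= 0 || hill_n <= 0) {
    stop("ca_half and hill_n must be > 0", call. = FALSE)
  }
  structure(list(g_max = g_max, ca_half = ca_half, hill_n = hill_n,
                 e_rev = e_rev), class = "ano1_params")
}

#' @rdname ano1_params
#' @param v Membrane potential (mV).
#' @param ca_i Intracellular Ca2+ (nM, >= 0).
#' @param params An `ano1_params` object.
#' @return `ano1_current()`: current in pA.
#' @export
ano1_current <- function(v, ca_i, params = ano1_params()) {
  stopifnot(inherits(params, "ano1_params"))
  if (any(ca_i < 0)) stop("ca_i must be >= 0", call. = FALSE)
  act <- ca_i^params$hill_n /
    (ca_i^params$hill_n + params$ca_half^params$hill_n)
  act[ca_i == 0] <- 0
  params$g_max * act * (v - params$e_rev)
}

#' Classical channel currents of the taste-cell frame
#'
#' Standard Hodgkin-Huxley algebraic current forms in pA:
#' `nav_current` is `g_na * m^3 * h * (v - e_na)`, `kdr_current` is
#' `g_k * n^4 * (v - e_k)`, and `leak_current` is `g_leak * (v - e_leak)`.
#' Gate values are supplied by the caller (instantaneous evaluation; the ODE
#' integrator owns the gate dynamics).
#'
#' @param v Membrane potential (mV).
#' @param m,h,n Gate open fractions in \[0, 1\].
#' @param g_na,g_k,g_leak Maximal conductances (nS).
#' @param e_na,e_k,e_leak Reversal potentials (mV).
#' @return Current in pA (positive = outward).
#' @export
nav_current <- function(v, m, h, g_na, e_na) {
  g_na * m^3 * h * (v - e_na)
}

#' @rdname nav_current
#' @export
kdr_current <- function(v, n, g_k, e_k) {
  g_k * n^4 * (v - e_k)
}

#' @rdname nav_current
#' @export
leak_current <- function(v, g_leak, e_leak) {
  g_leak * (v - e_leak)
}
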