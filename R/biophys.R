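# Physical constants (CODATA): gas constant J mol^-1 K^-1, Faraday C mol^-1.
.GAS_CONSTANT <- 8.314462618
.FARADAY <- 96485.332

#' Ionic conditions of a recording or simulation
#'
#' Bundles the intra- and extracellular Na+, K+ and Cl- concentrations and the
#' bath temperature. These fix every Nernst reversal potential in the model.
#' The defaults are the standard simulation conditions:
#' \[Na+\]o = 150, \[K+\]o = 5.4, \[Cl-\]o = 150, \[Na+\]i = 6, \[K+\]i = 140,
#' \[Cl-\]i = 30 (mM), at 25 degrees C (298.15 K), the temperature the
#' whole-cell recordings were held at.
#'
#' @param na_out,na_in Extra-/intracellular Na+ concentration (mM).
#' @param k_out,k_in Extra-/intracellular K+ concentration (mM).
#' @param cl_out,cl_in Extra-/intracellular Cl- concentration (mM).
#' @param temperature Absolute temperature (K); must lie in \[273, 320\].
#' @return An object of class `ionic_conditions`.
#' @examples
#' cond <- ionic_conditions()
#' reversal_set(cond)
#' @export
ionic_conditions <- function(na_out = 150, na_in = 6,
                             k_out = 5.4, k_in = 140,
                             cl_out = 150, cl_in = 30,
                             temperature = 298.15) {
  conc <- c(na_out = na_out, na_in = na_in, k_out = k_out, k_in = k_in,
            cl_out = cl_out, cl_in = cl_in)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all ionic concentrations must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature < 273 || temperature > 320) {
    stop("temperature must lie in [273, 320] K", call. = FALSE)
  }
  structure(as.list(c(conc, temperature = temperature)),
            class = "ionic_conditions")
}

#' @export
print.ionic_conditions <- function(x, ...) {
  cat("Ionic conditions (mM):\n")
  cat(sprintf("  Na+ %g out / %g in, K+ %g out / %g in, Cl- %g out / %g in\n",
              x$na_out, x$na_in, x$k_out, x$k_in, x$cl_out, x$cl_in))
  cat(sprintf("  temperature %.2f K\n", x$temperature))
  invisible(x)
}

#' Nernst equilibrium potential
#'
#' Computes the equilibrium (reversal) potential of a single ion species,
#' `(R*T / (z*F)) * ln(c_out / c_in)`, in millivolts. Concentrations are
#' treated as activities, the convention in conductance-based modelling.
#'
#' @param valence Signed integer charge of the ion (e.g. +1 for Na+, -1 for
#'   Cl-); must be non-zero.
#' @param c_in,c_out Intra- and extracellular concentration (mM); both > 0.
#' @param temperature Absolute temperature (K).
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(1, c_in = 6, c_out = 150)    # Na+, about +82.7 mV
#' nernst_potential(-1, c_in = 30, c_out = 150)  # Cl-, about -41.3 mV
#' @export
nernst_potential <- function(valence, c_in, c_out, temperature = 298.15) {
  if (length(valence) != 1 || !is.finite(valence) || valence == 0 ||
      valence != round(valence)) {
    stop("valence must be a non-zero signed integer", call. = FALSE)
  }
  if (any(!is.finite(c(c_in, c_out))) || any(c(c_in, c_out) <= 0)) {
    stop("concentrations must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive", call. = FALSE)
  }
  # RT/F in mV (about 25.693 mV at 298.15 K)
  rt_f <- 1000 * .GAS_CONSTANT * temperature / .FARADAY
  rt_f / valence * log(c_out / c_in)
}

#' Reversal potentials under a set of ionic conditions
#'
#' Evaluates the Na+, K+ and Cl- Nernst potentials for the given conditions.
#' Under the standard simulation conditions these are approximately
#' +82.7, -83.6 and -41.3 mV.
#'
#' @param conditions An [ionic_conditions()] object.
#' @return An object of class `reversal_set` with fields `e_na`, `e_k`,
#'   `e_cl` (mV).
#' @export
reversal_set <- function(conditions = ionic_conditions()) {
  stopifnot(inherits(conditions, "ionic_conditions"))
  structure(list(
    e_na = nernst_potential(1, conditions$na_in, conditions$na_out,
                            conditions$temperature),
    e_k = nernst_potential(1, conditions$k_in, conditions$k_out,
                           conditions$temperature),
    e_cl = nernst_potential(-1, conditions$cl_in, conditions$cl_out,
                            conditions$temperature)
  ), class = "reversal_set")
}

#' @export
print.reversal_set <- function(x, ...) {
  cat(sprintf("Reversal potentials (mV): E_Na %+.1f, E_K %+.1f, E_Cl %+.1f\n",
              x$e_na, x$e_k, x$e_cl))
  invisible(x)
}

#' Read or write ionic conditions as a YAML/JSON config block
#'
#' The on-disk keys are `na_out, na_in, k_out, k_in, cl_out, cl_in,
#' temperature_K`.
#'
#' @param x An `ionic_conditions` object.
#' @return `conditions_to_list()` returns a plain named list;
#'   `conditions_from_list()` re-validates and returns `ionic_conditions`.
#' @export
conditions_to_list <- function(x) {
  stopifnot(inherits(x, "ionic_conditions"))
  list(na_out = x$na_out, na_in = x$na_in, k_out = x$k_out, k_in = x$k_in,
       cl_out = x$cl_out, cl_in = x$cl_in, temperature_K = x$temperature)
}

#' @rdname conditions_to_list
#' @param lst A named list with the config keys.
#' @export
conditions_from_list <- function(lst) {
  ionic_conditions(na_out = lst$na_out, na_in = lst$na_in,
                   k_out = lst$k_out, k_in = lst$k_in,
                   cl_out = lst$cl_out, cl_in = lst$cl_in,
                   temperature = lst$temperature_K)
}
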