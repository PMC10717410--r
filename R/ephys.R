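#' Current-voltage relation from a sweep family
#'
#' One current value per sweep: the mean over a measurement window, paired
#' with the sweep's command potential. The default window (used throughout
#' the analyses) is the last 10 percent of the step, where the current is
#' quasi-steady.
#'
#' @param sweeps A [sweep_set()] of current traces sharing a time grid.
#' @param window Length-2 numeric `(from, to)` in ms, within the sweep
#'   duration; `NULL` selects the last 10 percent.
#' @return An object of class `iv_curve`: `voltages` (mV, increasing),
#'   `currents` (pA), `measurement_window` (ms).
#' @export
extract_iv <- function(sweeps, window = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"))
  t_end <- max(sweeps$traces[[1]]$times)
  if (is.null(window)) window <- c(0.9 * t_end, t_end)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be (from, to) with from < to", call. = FALSE)
  }
  if (window[1] < 0 || window[2] > t_end + 1e-9) {
    stop("measurement window lies outside the sweep duration", call. = FALSE)
  }
  ord <- order(sweeps$step_mv)
  currents <- vapply(ord, function(i) {
    tr <- sweeps$traces[[i]]
    sel <- tr$times >= window[1] & tr$times <= window[2]
    if (!any(sel)) stop("empty measurement window", call. = FALSE)
    mean(tr$values[sel])
  }, numeric(1))
  structure(list(voltages = sweeps$step_mv[ord], currents = currents,
                 measurement_window = window),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("I-V curve: %d points, %g .. %g mV, window %g-%g ms\n",
              length(x$voltages), min(x$voltages), max(x$voltages),
              x$measurement_window[1], x$measurement_window[2]))
  invisible(x)
}

#' @export
as.data.frame.iv_curve <- function(x, ...) {
  data.frame(v_mV = x$voltages, i_pA = x$currents)
}

#' Reversal potential from an I-V curve
#'
#' Linear interpolation of the zero-current crossing. Among adjacent
#' sign-change pairs the one whose currents are closest to 0 pA in magnitude
#' is used; if several crossings remain, the most negative-voltage crossing
#' is returned (the rectifier shape puts the physiological reversal there).
#' With no sign change the reversal is undeclared and an error is raised —
#' mirroring how very small inward currents can make the reversal impossible
#' to determine from a recording.
#'
#' @param iv An [extract_iv()] result.
#' @return Reversal potential (mV).
#' @export
estimate_reversal <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  v <- iv$voltages; i <- iv$currents
  cross <- which(i[-length(i)] * i[-1] <= 0 &
                   !(i[-length(i)] == 0 & i[-1] == 0))
  # exact zeros count as their own crossing
  exact <- which(i == 0)
  if (length(cross) == 0 && length(exact) == 0) {
    stop("no zero crossing: reversal potential cannot be determined",
         call. = FALSE)
  }
  if (length(exact) > 0) return(v[exact[1]])
  mag <- pmin(abs(i[cross]), abs(i[cross + 1]))
  best <- cross[mag == min(mag)]
  k <- best[1]  # most negative voltage among equally close crossings
  v[k] + (v[k + 1] - v[k]) * (0 - i[k]) / (i[k + 1] - i[k])
}

#' Pharmacological inhibition ratio
#'
#' `I_blocker / I_control` measured at a reference step potential
#' (+60 mV by default), each as the window-mean current of the matching
#' sweep. For a pure conductance blocker the ratio equals the conductance
#' multiplier and lies in \[0, 1\].
#'
#' @param control,blocker [sweep_set()] families containing the `at_v` step.
#' @param at_v Reference step potential (mV).
#' @param window Measurement window passed to [extract_iv()].
#' @return Dimensionless ratio.
#' @export
inhibition_ratio <- function(control, blocker, at_v = 60, window = NULL) {
  pick <- function(sweeps) {
    iv <- extract_iv(sweeps, window)
    j <- which(abs(iv$voltages - at_v) < 1e-6)
    if (length(j) != 1) {
      stop("sweep family lacks the ", at_v, " mV step", call. = FALSE)
    }
    iv$currents[j]
  }
  i_ctrl <- pick(control)
  i_blk <- pick(blocker)
  if (abs(i_ctrl) < 1) {
    stop("control current at ", at_v, " mV is ~0 pA; ratio undefined",
         call. = FALSE)
  }
  i_blk / i_ctrl
}

#' Detect action potentials in a voltage trace
#'
#' Local maxima above `threshold`, at least `min_separation` apart (when two
#' candidate peaks are closer, the larger is kept). Per-spike metrics use
#' central-difference derivatives on the uniform grid; duration is measured
#' between the trace's crossings of the detection threshold around the peak.
#'
#' @param trace A voltage [new_trace()].
#' @param threshold Detection threshold (mV).
#' @param min_separation Minimum peak separation (ms).
#' @return List of per-spike metric lists (class `ap_metrics`): `peak_v`,
#'   `peak_t`, `max_dvdt`, `min_dvdt` (mV/ms), `duration_at_threshold`
#'   (ms). Empty list when nothing crosses threshold.
#' @export
detect_aps <- function(trace, threshold = 0, min_separation = 5) {
  stopifnot(inherits(trace, "trace"), trace$kind == "voltage")
  v <- trace$values; t <- trace$times
  n <- length(v)
  if (n < 3) return(list())
  dv <- diff(v)
  cand <- which(dv[-length(dv)] > 0 & dv[-1] <= 0) + 1
  cand <- cand[v[cand] > threshold]
  if (length(cand) == 0) return(list())
  # enforce min_separation, keeping the larger peak of close pairs
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer()
  for (k in cand) {
    if (all(abs(t[k] - t[kept]) >= min_separation)) kept <- c(kept, k)
  }
  kept <- sort(kept)
  dt <- trace_dt(trace)
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  lapply(kept, function(k) {
    # spike support: from the previous to the next threshold crossing
    lo <- k; while (lo > 1 && v[lo - 1] > threshold) lo <- lo - 1
    hi <- k; while (hi < n && v[hi + 1] > threshold) hi <- hi + 1
    seg <- lo:hi
    structure(list(
      peak_v = v[k], peak_t = t[k],
      max_dvdt = max(dvdt[seg], na.rm = TRUE),
      min_dvdt = min(dvdt[max(1, lo - 1):min(n, hi + 1)], na.rm = TRUE),
      duration_at_threshold = t[hi] - t[lo]),
      class = "ap_metrics")
  })
}

#' Firing-train metrics
#'
#' Cycle length is the mean of all successive inter-peak intervals. With
#' fewer than two spikes the mean is reported as absent (`NA`), not zero.
#'
#' @param aps List of spike metrics from [detect_aps()].
#' @return Object of class `train_metrics`: `n_spikes`,
#'   `cycle_lengths` (ms), `cycle_length_mean` (ms or `NA`).
#' @export
cycle_length <- function(aps) {
  times <- vapply(aps, function(a) a$peak_t, numeric(1))
  cl <- if (length(times) >= 2) diff(times) else numeric()
  structure(list(n_spikes = length(times),
                 cycle_lengths = cl,
                 cycle_length_mean = if (length(cl)) mean(cl) else NA_real_),
            class = "train_metrics")
}

#' @export
print.train_metrics <- function(x, ...) {
  cat(sprintf("%d spikes; mean cycle length %s ms\n", x$n_spikes,
              if (is.na(x$cycle_length_mean)) "-" else
                sprintf("%.2f", x$cycle_length_mean)))
  invisible(x)
}

#' Extrema of the voltage time derivative
#'
#' Central-difference dV/dt extrema within a window (the whole trace by
#' default). The most negative value indexes repolarization speed; the most
#' positive, upstroke speed.
#'
#' @param trace A voltage [new_trace()].
#' @param window Optional `(from, to)` ms.
#' @return Named numeric `c(max_dvdt, min_dvdt)` in mV/ms.
#' @export
dvdt_extrema <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "trace"))
  v <- trace$values; t <- trace$times; n <- length(v)
  dt <- trace_dt(trace)
  dvdt <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  tc <- t[2:(n - 1)]
  if (!is.null(window)) {
    sel <- tc >= window[1] & tc <= window[2]
    if (!any(sel)) stop("window contains no samples", call. = FALSE)
    dvdt <- dvdt[sel]
  }
  c(max_dvdt = max(dvdt), min_dvdt = min(dvdt))
}
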