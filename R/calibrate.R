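# Session cache so repeated calls (tests, analysis scripts) calibrate once.
.tastecell_cache <- new.env(parent = emptyenv())

#' Calibrate the cell model to printed electrophysiological anchors
#'
#' Two-stage deterministic calibration:
#'
#' * Stage 1 (exact): with all other channels at their steady-state gates,
#'   the two fixed-point constraints `V(0 pA) = v_rest` and
#'   `V(i_hold) = v_held` are linear in `(g_leak, g_leak * e_leak)` and are
#'   solved in closed form.
#' * Stage 2 (one-dimensional root search): `g_na` is scaled so that the
#'   brief suprathreshold pulse protocol reaches `ap_peak`, then the result
#'   is verified to fire repetitively under the long -15 pA step.
#'
#' Default anchors are the printed values: resting potential -65 mV,
#' held at -70 mV under a +10 pA holding current, action-potential peak
#' +50 mV.
#'
#' @param anchors Named list `v_rest` (mV), `i_hold` (pA), `v_held` (mV),
#'   `ap_peak` (mV).
#' @param base Base [cell_params()] whose leak and `g_na` are replaced.
#' @param g_na_range Bracket for the stage-2 search (nS).
#' @param verify If `TRUE` (default), check all anchors on the returned
#'   parameters and that the -15 pA step evokes a spike train.
#' @return A calibrated `cell_params` object.
#' @export
calibrate_cell <- function(anchors = list(v_rest = -65, i_hold = 10,
                                          v_held = -70, ap_peak = 50),
                           base = default_cell_params(),
                           g_na_range = c(60, 250),
                           verify = TRUE) {
  need <- c("v_rest", "i_hold", "v_held", "ap_peak")
  if (!all(need %in% names(anchors))) {
    stop("anchors must name ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anchors$v_rest == anchors$v_held && anchors$i_hold != 0) {
    stop("calibration error: v_rest equals v_held but i_hold is non-zero",
         call. = FALSE)
  }
  p <- calibrate_leak(base, anchors)
  # Stage 2: scale g_na until the brief pulse reaches the target peak.
  proto <- protocol_brief_pulses(n_pulses = 1, amplitude = -140, width = 1,
                                 i_hold = anchors$i_hold, first_onset = 10,
                                 sample_dt = 0.02)
  proto$total_time <- 80
  peak_of <- function(g_na) {
    q <- p
    q$g_na <- g_na
    q <- calibrate_leak(q, anchors)
    max(simulate_current_clamp(q, proto)$values)
  }
  f <- function(g) peak_of(g) - anchors$ap_peak
  flo <- f(g_na_range[1]); fhi <- f(g_na_range[2])
  if (sign(flo) == sign(fhi)) {
    stop("calibration error: ap_peak anchor not bracketed by g_na_range",
         call. = FALSE)
  }
  g_na <- stats::uniroot(f, g_na_range, tol = 0.05)$root
  p$g_na <- g_na
  p <- calibrate_leak(p, anchors)
  if (verify) verify_calibration(p, anchors)
  p
}

# Stage 1: closed-form (g_leak, e_leak) from the two steady-state anchors.
calibrate_leak <- function(params, anchors) {
  p0 <- params
  p0$g_leak <- 0
  s_rest <- steady_ionic_current(anchors$v_rest, p0)
  s_held <- steady_ionic_current(anchors$v_held, p0)
  # g*(v_rest - e) + s_rest = 0 ; g*(v_held - e) + s_held = -i_hold
  g_leak <- (-anchors$i_hold - s_held + s_rest) /
    (anchors$v_held - anchors$v_rest)
  if (!is.finite(g_leak) || g_leak <= 0) {
    stop("calibration error: anchors require non-positive leak conductance",
         call. = FALSE)
  }
  e_leak <- anchors$v_rest + s_rest / g_leak
  params$g_leak <- g_leak
  params$e_leak <- e_leak
  params
}

verify_calibration <- function(params, anchors) {
  v0 <- steady_state(params, 0)[["v"]]
  vh <- steady_state(params, anchors$i_hold)[["v"]]
  if (abs(v0 - anchors$v_rest) > 0.5) {
    stop("calibration error: resting potential ", round(v0, 2),
         " misses anchor ", anchors$v_rest, call. = FALSE)
  }
  if (abs(vh - anchors$v_held) > 0.5) {
    stop("calibration error: held potential ", round(vh, 2),
         " misses anchor ", anchors$v_held, call. = FALSE)
  }
  tr <- simulate_current_clamp(
    params, protocol_current_step(sample_dt = 0.02))
  n_ap <- length(detect_aps(tr))
  if (n_ap < 2) {
    stop("calibration error: cell does not fire repetitively at -15 pA",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Calibrated default model (cached)
#'
#' Runs [calibrate_cell()] on the default anchors once per session and
#' caches the result; the calibration is deterministic, so the cache only
#' avoids recomputation.
#'
#' @param tmc4_factor TMC4 `scale_factor` to set on the calibrated model
#'   (the calibration itself is performed at factor 1).
#' @return A calibrated `cell_params` object.
#' @export
calibrated_cell_params <- function(tmc4_factor = 1) {
  if (is.null(.tastecell_cache$default_calibrated)) {
    .tastecell_cache$default_calibrated <- calibrate_cell()
  }
  p <- .tastecell_cache$default_calibrated
  p$tmc4$scale_factor <- tmc4_factor
  p
}
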