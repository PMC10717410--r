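#' Serialize a cell model to a YAML config and back
#'
#' Round-trips all parameter blocks (capacitance, conductances, gates, TMC4
#' block, ionic conditions) through a plain YAML mapping, so model variants
#' can be version-controlled and rerun.
#'
#' @param params A [cell_params()] object.
#' @param path File path (`.yaml`).
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a validated `cell_params`.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "cell_params"))
  gate_lst <- function(g) {
    list(v_half = g$v_half, slope_k = g$slope_k, tau_min = g$tau_min,
         tau_max = g$tau_max, exponent = g$exponent)
  }
  cfg <- list(
    cm = params$cm,
    g_na = params$g_na, g_k = params$g_k, g_leak = params$g_leak,
    e_leak = params$e_leak,
    m_gate = gate_lst(params$m_gate),
    h_gate = gate_lst(params$h_gate),
    n_gate = gate_lst(params$n_gate),
    tmc4 = list(g_max = params$tmc4$g_max,
                scale_factor = params$tmc4$scale_factor,
                v_half = params$tmc4$v_half, slope_k = params$tmc4$slope_k,
                e_rev_mode = params$tmc4$e_rev_mode,
                e_rev_fixed = params$tmc4$e_rev_fixed,
                anion_scale = as.list(params$tmc4$anion_scale),
                tau_act = params$tmc4$tau_act,
                block_factor = params$tmc4$block_factor),
    conditions = conditions_to_list(params$conditions))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gate_obj <- function(g) {
    hh_gate(g$v_half, g$slope_k, g$tau_min, g$tau_max, g$exponent)
  }
  tm <- cfg$tmc4
  cell_params(
    cm = cfg$cm, g_na = cfg$g_na, g_k = cfg$g_k, g_leak = cfg$g_leak,
    e_leak = cfg$e_leak,
    m_gate = gate_obj(cfg$m_gate), h_gate = gate_obj(cfg$h_gate),
    n_gate = gate_obj(cfg$n_gate),
    tmc4 = tmc4_params(g_max = tm$g_max, scale_factor = tm$scale_factor,
                       v_half = tm$v_half, slope_k = tm$slope_k,
                       e_rev_mode = tm$e_rev_mode,
                       e_rev_fixed = tm$e_rev_fixed,
                       anion_scale = unlist(tm$anion_scale),
                       tau_act = tm$tau_act,
                       block_factor = tm$block_factor),
    conditions = conditions_from_list(cfg$conditions))
}
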