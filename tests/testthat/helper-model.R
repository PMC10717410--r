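# Calibrated model shared across tests; calibrate_cell() caches per session.
calib <- function(tmc4_factor = 1) calibrated_cell_params(tmc4_factor)

# A leak-only cell: closed-form steady states for oracle checks.
leak_only_cell <- function(g_leak = 2, e_leak = -65) {
  cell_params(g_na = 0, g_k = 0, g_leak = g_leak, e_leak = e_leak,
              tmc4 = tmc4_params(g_max = 0))
}

# Step protocol used by the synthetic recovery experiments: 5 mV steps give
# the interpolated reversal a fine voltage grid, 400 ms at 0.5 ms sampling
# gives the measurement window enough samples to average the noise down.
recovery_protocol <- function() {
  voltage_clamp_protocol(step_from = -100, step_to = 100,
                         step_increment = 5, step_duration = 400,
                         sample_dt = 0.5)
}

# Scratch directory cleaned up when the test process exits.
withr_like_tempdir <- function() {
  d <- file.path(tempdir(), paste0("tastecell-", as.integer(stats::runif(1, 1, 1e8))))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
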