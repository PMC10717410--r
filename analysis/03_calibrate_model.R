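#!/usr/bin/env Rscript
# Stage 3: calibrate the whole-cell taste-cell model.
#
# Anchors: resting potential -65 mV at 0 pA; -70 mV under a +10 pA holding
# current; action-potential peak +50 mV under brief -140 pA pulses. Stage 1
# solves the leak conductance and reversal exactly from the two steady-state
# constraints; stage 2 root-finds the Na+ conductance for the spike peak and
# verifies repetitive firing under the long -15 pA step.

suppressPackageStartupMessages(library(tastecell))

out_dir <- "results/model"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- calibrate_cell()

v_rest <- steady_state(params, 0)[["v"]]
v_held <- steady_state(params, 10)[["v"]]
i_hold <- find_holding_current(params, -70)
cat(sprintf("calibrated: g_Na %.2f nS, g_leak %.3f nS, E_leak %.2f mV\n",
            params$g_na, params$g_leak, params$e_leak))
cat(sprintf("checks: V_rest %.3f mV, V_held %.3f mV, I_hold(-70) %.3f pA\n",
            v_rest, v_held, i_hold))

write_model_config(params, file.path(out_dir, "calibrated_model.yaml"))
jsonlite::write_json(
  list(anchors = list(v_rest = -65, i_hold = 10, v_held = -70,
                      ap_peak = 50),
       achieved = list(v_rest = v_rest, v_held = v_held, i_hold = i_hold),
       g_na = params$g_na, g_leak = params$g_leak,
       e_leak = params$e_leak),
  file.path(out_dir, "calibration_summary.json"),
  auto_unbox = TRUE, digits = NA)
cat("wrote", out_dir, "\n")
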