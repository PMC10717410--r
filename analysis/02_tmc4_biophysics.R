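#!/usr/bin/env Rscript
# Stage 2: TMC4 channel biophysics in the heterologous-expression
# configuration.
#
# Reproduces the whole-cell characterisation in silico: step-pulse I-V
# families with KCl and NMDG-Cl pipette reversal potentials, outward
# rectification, pharmacological block as conductance multipliers, anion
# substitution as amplitude-only scaling, and the Ca2+-insensitivity
# contrast with ANO1.

suppressPackageStartupMessages(library(tastecell))

out_dir <- "results/biophysics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
steps <- voltage_clamp_protocol()  # -100..+100 mV by 10, 400 ms, from -60

## I-V families and reversal potentials -----------------------------------
for (pip in c("kcl", "nmdg")) {
  p <- hek_cell_params(pip)
  sweeps <- simulate_voltage_clamp(p, steps)
  iv <- extract_iv(sweeps)
  er <- estimate_reversal(iv)
  rect <- abs(iv$currents[iv$voltages == -100]) /
    abs(iv$currents[iv$voltages == 100])
  cat(sprintf("%s pipette: Er = %.2f mV, |I(-100)|/|I(+100)| = %.4f\n",
              toupper(pip), er, rect))
  utils::write.csv(as.data.frame(iv),
                   file.path(out_dir, paste0("iv_", pip, ".csv")),
                   row.names = FALSE)
}

## pharmacology: block as a conductance multiplier -------------------------
# The recordings report relative inhibition only as bar graphs, so no
# numeric block value is asserted by the package; the multipliers below are
# illustrative config inputs spanning strong to absent block.
blockers <- c(strong_block = 0.1, partial_block = 0.5, no_block = 1.0)
ctrl <- simulate_voltage_clamp(hek_cell_params("kcl"), steps)
ratios <- vapply(blockers, function(b) {
  p <- hek_cell_params("kcl")
  p$tmc4$block_factor <- b
  inhibition_ratio(ctrl, simulate_voltage_clamp(p, steps), at_v = 60)
}, numeric(1))
cat("inhibition ratios I_blocker/I_control at +60 mV:\n")
print(round(ratios, 4))

## anion substitution: amplitude scales, reversal does not ----------------
anions <- c(chloride = 1, bromide = 0.9, iodide = 0.75, acetate = 0.5,
            gluconate = 0.3, methanesulfonate = 0.4)
anion_rows <- lapply(names(anions), function(an) {
  p <- hek_cell_params("kcl")
  p$tmc4$anion_scale <- anions
  i60 <- tmc4_current(60, p$tmc4, anion = an)
  # amplitude-scaled I-V keeps its zero crossing
  v <- seq(-100, 100, 10)
  iv <- structure(list(voltages = v,
                       currents = tmc4_current(v, p$tmc4, anion = an),
                       measurement_window = c(0, 0)), class = "iv_curve")
  data.frame(anion = an, scale = anions[[an]], i_60mV_pA = i60,
             reversal_mV = estimate_reversal(iv))
})
anion_tab <- do.call(rbind, anion_rows)
print(anion_tab, row.names = FALSE)
utils::write.csv(anion_tab, file.path(out_dir, "anion_substitution.csv"),
                 row.names = FALSE)

## Ca2+ sensitivity: TMC4 flat, ANO1 graded --------------------------------
ca <- c(0, 100, 250, 500, 1000, 2000)
ca_tab <- data.frame(
  ca_nM = ca,
  tmc4_pA = vapply(ca, function(c)
    tmc4_current(60, hek_cell_params("kcl")$tmc4, ca_i = c), numeric(1)),
  ano1_pA = ano1_current(60, ca, ano1_params()))
print(ca_tab, row.names = FALSE)
utils::write.csv(ca_tab, file.path(out_dir, "ca_sensitivity.csv"),
                 row.names = FALSE)
cat("wrote", out_dir, "\n")
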