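test_that("current clamp holds the cell at the holding potential", {
  p <- calib()
  proto <- current_clamp_protocol(i_hold = 10, total_time = 200,
                                  sample_dt = 0.05)
  tr <- simulate_current_clamp(p, proto)
  expect_equal(tail(tr$values, 1), -70, tolerance = 0.5 / 70)
  expect_lt(diff(range(tr$values)), 0.01)  # no drift from the fixed point
})

test_that("current-clamp simulation is deterministic and convergent", {
  p <- calib()
  proto <- protocol_brief_pulses(n_pulses = 1, sample_dt = 0.02)
  tr1 <- simulate_current_clamp(p, proto)
  tr2 <- simulate_current_clamp(p, proto)
  expect_identical(tr1$values, tr2$values)
  # halving tolerances moves sampled voltages by far less than 0.1 mV
  tr3 <- simulate_current_clamp(p, proto, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(tr1$values - tr3$values)), 0.1)
})

test_that("short pulses are never stepped over by the integrator", {
  p <- calib()
  proto <- protocol_brief_pulses(n_pulses = 3, sample_dt = 0.02)
  aps <- detect_aps(simulate_current_clamp(p, proto))
  expect_length(aps, 3)
  # one spike inside each 500 ms pulse window
  peak_t <- vapply(aps, function(a) a$peak_t, numeric(1))
  expect_equal(findInterval(peak_t, c(0, 500, 1000, 1500)), 1:3)
})

test_that("voltage-clamp step family matches the protocol arithmetic", {
  p <- hek_cell_params("kcl")
  sweeps <- simulate_voltage_clamp(p, voltage_clamp_protocol())
  expect_length(sweeps, 21)
  expect_equal(sweeps$step_mv, seq(-100, 100, 10))
  # zero driving force at the fixed reversal: inject a step right at E_rev
  proto1 <- voltage_clamp_protocol(step_from = -27.6, step_to = -27.6,
                                   step_increment = 10)
  i_rev <- simulate_voltage_clamp(p, proto1)$traces[[1]]$values
  expect_equal(max(abs(i_rev)), 0, tolerance = 1e-9)
})

test_that("voltage-clamp steady currents equal the algebraic channel sum", {
  # TMC4-only configuration: +60 mV steady current is the closed form
  p <- hek_cell_params("kcl")
  iv <- extract_iv(simulate_voltage_clamp(p, voltage_clamp_protocol()))
  expect_equal(iv$currents[iv$voltages == 60], 803, tolerance = 1 / 803)
  expect_equal(iv$currents[iv$voltages == 60],
               tmc4_current(60, p$tmc4), tolerance = 1e-9)
})

test_that("ramp voltage clamp tracks the commanded voltage", {
  p <- hek_cell_params("kcl")
  proto <- voltage_clamp_protocol(mode = "ramp", sample_dt = 0.5)
  tr <- simulate_voltage_clamp(p, proto)$traces[[1]]
  # instantaneous TMC4 gating: ramp current is the algebraic I(V(t))
  v_t <- -100 + (200 / 300) * tr$times
  expect_equal(tr$values, tmc4_current(v_t, p$tmc4), tolerance = 1e-6)
})

test_that("conductance sweep only changes the TMC4 scale factor", {
  p <- calib()
  proto <- protocol_current_step(duration = 120, sample_dt = 0.05)
  sw <- conductance_sweep(p, c(1, 1), proto)
  expect_identical(sw$traces[[1]]$values, sw$traces[[2]]$values)
  sw0 <- conductance_sweep(p, 0, proto)
  p0 <- p; p0$tmc4$scale_factor <- 0
  expect_identical(sw0$traces[[1]]$values,
                   simulate_current_clamp(p0, proto)$values)
  expect_error(conductance_sweep(p, -1, proto), ">= 0")
})

test_that("protocol validation catches malformed pulse tables", {
  expect_error(current_clamp_protocol(
    pulses = data.frame(onset = 900, duration = 200, amplitude = -15),
    total_time = 1000), "within")
  expect_error(current_clamp_protocol(
    pulses = data.frame(onset = c(10, 15), duration = c(10, 10),
                        amplitude = c(-15, -15)),
    total_time = 100), "overlap")
  expect_error(voltage_clamp_protocol(step_increment = 0), "step_increment")
})
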