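test_that("TMC4 activation is a Boltzmann with the right midpoint and limits", {
  p <- tmc4_params()
  expect_equal(tmc4_activation(p$v_half, p), 0.5)
  expect_equal(tmc4_activation(-1e4, p), 0, tolerance = 1e-12)
  expect_equal(tmc4_activation(1e4, p), 1)
  # monotone in v
  v <- seq(-100, 100, 5)
  expect_true(all(diff(tmc4_activation(v, p)) > 0))
  # frozen value at +60 mV under the channel defaults (v_half 0, k 25)
  expect_equal(tmc4_activation(60, p), 0.9168, tolerance = 1e-3)
})

test_that("TMC4 current follows the ohmic Boltzmann form", {
  p <- tmc4_params()  # g 10 nS, fixed E_rev -27.6 mV
  expect_equal(tmc4_current(-27.6, p), 0)
  expect_equal(tmc4_current(60, p), 803, tolerance = 1 / 803)
  # scale_factor 0 kills the current everywhere
  p0 <- p; p0$scale_factor <- 0
  expect_equal(tmc4_current(seq(-100, 100, 10), p0), rep(0, 21))
})

test_that("TMC4 current is exactly linear in scale, block and anion factors", {
  v <- seq(-100, 100, 20)
  base <- tmc4_params(anion_scale = c(chloride = 1, gluconate = 0.4))
  i1 <- tmc4_current(v, base)
  for (s in c(0.25, 1.5, 3)) {
    ps <- base; ps$scale_factor <- s
    expect_equal(tmc4_current(v, ps), s * i1)
    pb <- base; pb$block_factor <- min(s, 1)
    expect_equal(tmc4_current(v, pb), min(s, 1) * i1)
  }
  expect_equal(tmc4_current(v, base, anion = "gluconate"), 0.4 * i1)
  expect_error(tmc4_current(0, base, anion = "sulfate"), "unknown anion")
})

test_that("TMC4 rectifies outwardly and reversal ignores anion amplitude", {
  p <- tmc4_params()
  expect_lt(abs(tmc4_current(-100, p)), 0.15 * abs(tmc4_current(100, p)))
  expect_true(all(diff(tmc4_current(seq(-27, 100, 1), p)) > 0))
  # zero crossing is invariant under any anion amplitude factor
  v <- seq(-100, 100, 0.5)
  p2 <- tmc4_params(anion_scale = c(chloride = 1, acetate = 0.15))
  for (an in c("chloride", "acetate")) {
    i <- tmc4_current(v, p2, anion = an)
    crossing <- v[which(diff(sign(i)) > 0)]
    expect_equal(crossing, -28, tolerance = 1e-6)  # grid point below -27.6
  }
})

test_that("TMC4 ignores Ca2+ while ANO1 increases with it", {
  p <- tmc4_params()
  ca <- c(0, 100, 500, 1e6)
  i_tmc4 <- vapply(ca, function(c) tmc4_current(60, p, ca_i = c), numeric(1))
  expect_true(all(i_tmc4 == i_tmc4[1]))

  a <- ano1_params()
  expect_equal(ano1_current(60, 0, a), 0)
  # Hill midpoint: half the fully activated current
  expect_equal(ano1_current(60, a$ca_half, a),
               0.5 * a$g_max * (60 - a$e_rev))
  # monotone in Ca2+ at a potential above reversal (ionomycin-style step)
  i_ano1 <- ano1_current(60, ca, a)
  expect_true(all(diff(i_ano1) > 0))
  expect_error(ano1_current(0, -1, a), ">= 0")
})

test_that("HH gate kinetics relax first-order towards the Boltzmann", {
  g <- hh_gate(-40, 6, 0.5, 4, 2L)
  expect_equal(gate_steady_state(-40, g), 0.5)
  expect_equal(gate_derivative(gate_steady_state(-55, g), -55, g), 0)
  tau <- gate_tau(seq(-120, 60, 2), g)
  expect_true(all(tau >= g$tau_min & tau <= g$tau_max))
  # closed-form relaxation from x = 0 at fixed voltage: 1 - exp(-t/tau)
  v_fix <- -30
  tau0 <- gate_tau(v_fix, g)
  xi <- gate_steady_state(v_fix, g)
  out <- deSolve::lsoda(c(x = 0), seq(0, 10, 0.1),
                        function(t, y, p) list(gate_derivative(y, v_fix, g)),
                        NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(out[, 2], xi * (1 - exp(-out[, 1] / tau0)), tolerance = 1e-6)
})

test_that("classical currents vanish at their reversals and obey HH forms", {
  expect_equal(nav_current(82.7, 0.5, 0.5, 100, 82.7), 0)
  expect_equal(kdr_current(-83.6, 0.5, 30, -83.6), 0)
  expect_equal(leak_current(-65, 2, -65), 0)
  # fully open Na channel is ohmic
  expect_equal(nav_current(0, 1, 1, 120, 82.7), 120 * (0 - 82.7))
  # gates at rest give small currents directed at their reversals
  p <- default_cell_params()
  v <- -70
  i_na <- nav_current(v, gate_steady_state(v, p$m_gate),
                      gate_steady_state(v, p$h_gate), p$g_na,
                      p$reversals$e_na)
  i_k <- kdr_current(v, gate_steady_state(v, p$n_gate), p$g_k,
                     p$reversals$e_k)
  expect_lt(i_na, 0); expect_gt(abs(i_na), 0)
  expect_gt(i_k, 0)
  expect_lt(abs(i_na) + abs(i_k), 5)
})

test_that("channel parameter validation rejects out-of-range values", {
  expect_error(tmc4_params(slope_k = -5), "slope_k")
  expect_error(tmc4_params(block_factor = 1.5), "block_factor")
  expect_error(tmc4_params(anion_scale = c(bromide = 0.9)), "chloride")
  expect_error(hh_gate(0, 0, 1, 2), "slope_k")
  expect_error(hh_gate(0, 5, 3, 2), "tau_min")
  expect_error(ano1_params(ca_half = 0), "> 0")
})
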