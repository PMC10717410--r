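make_const_sweeps <- function(currents, steps, t_end = 100, dt = 1) {
  tt <- seq(0, t_end, dt)
  sweep_set(lapply(currents, function(i) {
    new_trace(tt, rep(i, length(tt)), kind = "current")
  }), steps)
}

test_that("extract_iv reduces constant sweeps to their constants", {
  sw <- make_const_sweeps(c(-5, 0, 12), c(-40, -20, 0))
  iv <- extract_iv(sw)
  expect_equal(iv$voltages, c(-40, -20, 0))
  expect_equal(iv$currents, c(-5, 0, 12))
  expect_error(extract_iv(sw, window = c(200, 300)), "outside")
  expect_error(extract_iv(sw, window = c(50, 50)), "from < to")
})

test_that("reversal estimation is exact on affine I-V data", {
  # property sweep over slope and intercept
  set.seed(7)
  for (i in 1:20) {
    g <- runif(1, 0.5, 20)
    er <- runif(1, -80, 20)
    v <- seq(-100, 100, 10)
    sw <- make_const_sweeps(g * (v - er), v)
    expect_equal(estimate_reversal(extract_iv(sw)), er, tolerance = 1e-9)
  }
})

test_that("reversal estimation fails cleanly without a sign change", {
  sw <- make_const_sweeps(c(1, 5, 20), c(-50, 0, 50))
  expect_error(estimate_reversal(extract_iv(sw)), "no zero crossing")
})

test_that("inhibition ratio recovers conductance multipliers", {
  v <- seq(-100, 100, 10)
  ctrl <- make_const_sweeps(2 * (v + 27.6), v)
  expect_equal(inhibition_ratio(ctrl, ctrl), 1)
  zero <- make_const_sweeps(rep(0, length(v)), v)
  expect_equal(inhibition_ratio(ctrl, zero), 0)
  expect_error(inhibition_ratio(zero, ctrl), "undefined")
  # scale invariance: c * both families leaves the ratio unchanged
  half <- make_const_sweeps(1 * (v + 27.6), v)
  r <- inhibition_ratio(ctrl, half)
  big_c <- make_const_sweeps(14 * (v + 27.6), v)
  big_h <- make_const_sweeps(7 * (v + 27.6), v)
  expect_equal(inhibition_ratio(big_c, big_h), r)
  expect_equal(r, 0.5)
})

test_that("spike detection recovers known peak times", {
  flat <- gen_ap_trace(numeric(), total_time = 300, baseline = -70)
  expect_length(detect_aps(flat), 0)

  tr <- gen_ap_trace(c(100, 200, 300), total_time = 400)
  aps <- detect_aps(tr)
  expect_length(aps, 3)
  peak_t <- vapply(aps, function(a) a$peak_t, numeric(1))
  expect_equal(peak_t, tr$metadata$peak_times, tolerance = 0.051 / 100)
  expect_true(all(vapply(aps, function(a) a$peak_v, 1) > 49))

  # two merged peaks closer than min_separation: keep the larger
  t2 <- gen_ap_trace(c(100, 102), total_time = 200)
  aps2 <- detect_aps(t2, min_separation = 5)
  expect_length(aps2, 1)
  expect_equal(aps2[[1]]$peak_v, max(t2$values))
})

test_that("spike detection is invariant to a common baseline shift", {
  tr <- gen_ap_trace(c(50, 150), total_time = 250)
  shifted <- new_trace(tr$times, tr$values + 20, kind = "voltage")
  a0 <- detect_aps(tr, threshold = 0)
  a1 <- detect_aps(shifted, threshold = 20)
  expect_equal(vapply(a0, function(a) a$peak_t, 1),
               vapply(a1, function(a) a$peak_t, 1))
})

test_that("cycle length averages successive peak intervals", {
  tr <- gen_ap_trace(c(100, 200, 300), total_time = 400)
  cl <- cycle_length(detect_aps(tr))
  expect_equal(cl$n_spikes, 3)
  expect_equal(cl$cycle_length_mean, 100, tolerance = 1e-6)

  one <- cycle_length(detect_aps(gen_ap_trace(150, total_time = 300)))
  expect_equal(one$n_spikes, 1)
  expect_true(is.na(one$cycle_length_mean))

  # jittered spacing: the mean interval is (last - first)/(n - 1)
  times <- c(100, 196, 311, 402)
  clj <- cycle_length(detect_aps(gen_ap_trace(times, total_time = 500)))
  expect_equal(clj$cycle_length_mean, (402 - 100) / 3, tolerance = 1e-3)
})

test_that("dV/dt extrema match closed-form derivatives", {
  # linear ramp: derivative is the slope everywhere
  tt <- seq(0, 100, 0.1)
  ramp <- new_trace(tt, -70 + 0.25 * tt, kind = "voltage")
  expect_equal(dvdt_extrema(ramp), c(max_dvdt = 0.25, min_dvdt = 0.25),
               tolerance = 1e-9)
  # Gaussian spike: analytic extrema +-A exp(-1/2)/sigma at t0 -+ sigma
  A <- 120; sigma <- 1.5; t0 <- 50
  tt <- seq(0, 100, 0.01)
  gauss <- new_trace(tt, -70 + A * exp(-(tt - t0)^2 / (2 * sigma^2)),
                     kind = "voltage")
  ex <- dvdt_extrema(gauss)
  expect_equal(ex[["max_dvdt"]], A * exp(-0.5) / sigma, tolerance = 0.01)
  expect_equal(ex[["min_dvdt"]], -A * exp(-0.5) / sigma, tolerance = 0.01)
})
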