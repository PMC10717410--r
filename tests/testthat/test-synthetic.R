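test_that("noise-free generated sweeps equal the clean simulation", {
  p <- hek_cell_params("kcl")
  proto <- voltage_clamp_protocol(sample_dt = 2)
  clean <- simulate_voltage_clamp(p, proto)
  gen <- gen_vc_sweeps(p, proto, sd = 0, seed = 1)
  expect_identical(lapply(gen$traces, `[[`, "values"),
                   lapply(clean$traces, `[[`, "values"))
})

test_that("generators are pure functions of parameters and seed", {
  p <- hek_cell_params("kcl")
  proto <- voltage_clamp_protocol(sample_dt = 2)
  g1 <- gen_vc_sweeps(p, proto, sd = 5, seed = 11)
  g2 <- gen_vc_sweeps(p, proto, sd = 5, seed = 11)
  g3 <- gen_vc_sweeps(p, proto, sd = 5, seed = 12)
  expect_identical(g1$traces[[1]]$values, g2$traces[[1]]$values)
  expect_false(identical(g1$traces[[1]]$values, g3$traces[[1]]$values))

  t1 <- gen_ap_trace(c(10, 30), total_time = 50, sd = 1, seed = 4)
  t2 <- gen_ap_trace(c(10, 30), total_time = 50, sd = 1, seed = 4)
  expect_identical(t1$values, t2$values)

  e1 <- gen_expression_table(100, 10, seed = 21)
  e2 <- gen_expression_table(100, 10, seed = 21)
  expect_identical(e1, e2)

  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(gen_expression_table(50, 5, seed = 9))
  expect_identical(runif(5), before)
})

test_that("generated fixtures satisfy their own declared ground truth", {
  tr <- gen_ap_trace(c(40, 90, 140), total_time = 200, peak_v = 45)
  aps <- detect_aps(tr)
  expect_length(aps, 3)
  expect_equal(vapply(aps, function(a) a$peak_t, 1),
               tr$metadata$peak_times, tolerance = 0.051 / 40)
  # sampled maximum sits within one grid step of the continuous peak
  expect_equal(max(tr$values), 45, tolerance = 0.005)

  flat <- gen_ap_trace(numeric(), total_time = 100, baseline = -64)
  expect_true(all(flat$values == -64))

  tab <- gen_expression_table(300, 0, seed = 8)
  expect_length(screen_candidates(tab)$passing, 0)
})

test_that("trace, sweep and model-config files round-trip", {
  dir <- withr_like_tempdir()
  tr <- gen_ap_trace(c(25, 60), total_time = 100, sample_dt = 0.1)
  f <- file.path(dir, "trace.csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$values, tr$values, tolerance = 1e-9)
  expect_equal(back$kind, "voltage")
  expect_true(file.exists(paste0(f, ".json")))

  p <- hek_cell_params("nmdg")
  sw <- gen_vc_sweeps(p, voltage_clamp_protocol(sample_dt = 10),
                      sd = 2, seed = 3)
  g <- file.path(dir, "sweeps.csv")
  write_sweeps_csv(sw, g)
  back_sw <- read_sweeps_csv(g)
  expect_equal(back_sw$step_mv, sw$step_mv)
  expect_equal(back_sw$traces[[5]]$values, sw$traces[[5]]$values,
               tolerance = 1e-9)

  cfg <- file.path(dir, "model.yaml")
  pc <- default_cell_params()
  write_model_config(pc, cfg)
  back_p <- read_model_config(cfg)
  expect_equal(back_p$tmc4$slope_k, pc$tmc4$slope_k)
  expect_equal(back_p$reversals, pc$reversals)
  expect_equal(back_p$m_gate, pc$m_gate)
})
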