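test_that("Nernst potassium reversal follows the stated constants", {
  expect_equal(nernst_EK(140, 140), 0)
  expect_equal(nernst_EK(30, 140, 25.7), -39.6, tolerance = 0.002)
  expect_equal(nernst_EK(5, 140, 25.7), -85.6, tolerance = 0.001)
  expect_error(nernst_EK(-1, 140), "positive")
})

test_that("parameter containers validate and presets compose", {
  expect_error(model_params(C_m = -1), "C_m")
  expect_error(model_params(g_naf = -5), "non-negative")
  expect_error(model_params(bogus = 1), "unknown model parameter")
  expect_error(treatment_preset("kcl24h", s_na = 1.2), "0 < s_na < 1")
  expect_error(treatment_preset("control", s_na = 0.5), "s_na = 1")

  p <- apply_presets(model_params(), "delayed", "kcl24h")
  expect_equal(p$g_ka, model_params()$g_ka * 9 * 1.15)
  expect_equal(p$g_naf, model_params()$g_naf * 0.45)
  pk <- apply_presets(model_params(), "repeated", "acute_kcl")
  expect_equal(pk$K_out, 30)
  expect_equal(pk$g_naf, model_params()$g_naf)
})

test_that("simulation is deterministic given the seed", {
  p <- model_params()
  proto <- make_protocol("cc_step", "mouse")
  a <- simulate_cc_sweep(p, proto, 6, seed = 123)
  b <- simulate_cc_sweep(p, proto, 6, seed = 123)
  expect_identical(a$recorded, b$recorded)
  c <- simulate_cc_sweep(p, proto, 6, seed = 124)
  expect_false(identical(a$recorded, c$recorded))
})

test_that("resting potential calibration windows hold", {
  p <- model_params()
  zero <- make_protocol("cc_zero", "mouse")
  vr <- resting_potential(simulate_cc_sweep(p, zero, 1, seed = 2))
  expect_gt(vr$V_rest, -75); expect_lt(vr$V_rest, -40)
  expect_true(vr$included)

  pk <- apply_presets(p, "repeated", "acute_kcl")
  sw <- simulate_cc_sweep(pk, zero, 1, seed = 3)
  steady <- mean(sw$recorded[45001:55000])
  expect_gt(steady, -20); expect_lt(steady, -10)
})

test_that("raising bath potassium depolarizes the resting potential", {
  zero <- make_protocol("cc_zero", "mouse")
  v <- vapply(c(5, 10, 20), function(ko) {
    p <- model_params(K_out = ko, noise_sigma = 0)
    mean(simulate_cc_sweep(p, zero, 1)$recorded[45001:55000])
  }, 0)
  expect_true(all(diff(v) > 0))
})

test_that("no sodium conductance means no spikes", {
  p <- model_params(g_naf = 0, g_nas = 0)
  proto <- make_protocol("cc_step", "mouse")
  for (k in c(5, 10, 20)) {
    sw <- simulate_cc_sweep(p, proto, k, seed = 4)
    expect_equal(nrow(detect_aps(sw)), 0)
  }
})

test_that("true rheobase is monotone in the spike conductances", {
  base <- model_params(noise_sigma = 0.05)
  r_naf <- vapply(c(120, 160, 220), function(g)
    true_rheobase(model_params(g_naf = g, noise_sigma = 0.05), "cc_step",
                  cell_seed = 77)$rheobase, 0)
  expect_true(all(diff(r_naf) <= 0))
  r_kdr <- vapply(c(120, 200, 300), function(g)
    true_rheobase(model_params(g_kdr = g, noise_sigma = 0.05), "cc_step",
                  cell_seed = 77)$rheobase, 0)
  expect_true(all(diff(r_kdr) >= 0))
})

test_that("voltage clamp with a leak-only mask is exactly ohmic", {
  p <- model_params()
  rec <- simulate_voltage_clamp(p, make_protocol("vc_na_step"), "leak")
  EK <- nernst_EK(p$K_out, p$K_in, p$RT_over_F)
  for (sw in rec$sweeps$vc_na_step) {
    pred <- p$g_leakk * (sw$command - EK) + p$g_leakns * (sw$command - p$E_leakns)
    expect_equal(sw$recorded, pred, tolerance = 1e-12)
  }
})

test_that("voltage-clamp peak currents are linear in the conductances", {
  proto <- make_protocol("vc_na_ramp")
  peak_of <- function(p) {
    rec <- simulate_voltage_clamp(p, proto, c("naf", "nas"))
    min(rec$sweeps$vc_na_ramp[[1]]$recorded)
  }
  full <- peak_of(model_params())
  half <- peak_of(model_params(g_naf = model_params()$g_naf / 2,
                               g_nas = model_params()$g_nas / 2))
  expect_equal(half / full, 0.5, tolerance = 0.02)
})

test_that("sodium step IV peaks in the high-voltage-activated range", {
  rec <- simulate_voltage_clamp(model_params(), make_protocol("vc_na_step"),
                                c("naf", "nas", "leak"))
  fam <- rec$sweeps$vc_na_step
  leak <- fit_leak(fam[1:2], c(-85, -55), -80)
  iv <- step_iv(lapply(fam, leak_subtract, leak = leak), 25)
  v_min <- iv$v[which.min(iv$peak)]
  expect_gte(v_min, -20); expect_lte(v_min, 0)
})

test_that("cohort generation is bit-reproducible and carries ground truth", {
  cfg <- cohort_config(n_per_group = 2, groups = c("control", "kcl"),
                       seed = 7, families = c("cc_zero", "cc_step"),
                       compute_truth = FALSE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- generate_cohort(cfg, out_dir = d1)
  c2 <- generate_cohort(cfg, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_identical(names(c1$recordings), c("control_001", "control_002",
                                           "kcl_001", "kcl_002"))
  expect_error(generate_cohort(cohort_config(n_per_group = 0)),
               "positive")
})

test_that("treatment scaling raises true rheobase above the control twin", {
  p_ctl <- apply_presets(model_params(), "repeated", "control")
  p_kcl <- apply_presets(model_params(), "repeated", "kcl24h")
  r_ctl <- true_rheobase(p_ctl, "cc_ramp", cell_seed = 5)
  r_kcl <- true_rheobase(p_kcl, "cc_ramp", cell_seed = 5)
  expect_gt(r_kcl$rheobase, r_ctl$rheobase)
})

test_that("gating kinetics are frozen (regression pins)", {
  gt <- gating_tables(c(-42, -15, -12, -34, -52), model_params())
  # midpoints of the frozen Boltzmann curves
  expect_equal(gt$mf_inf[1], 0.5)
  expect_equal(gt$ms_inf[2], 0.5)
  expect_equal(gt$n_inf[3], 0.5)
  expect_equal(gt$a_inf[4], 0.5)
  expect_equal(gt$hf_inf[5], 0.007 + 0.993 / 2)
  # floors: persistent sodium and A-current availability
  gt2 <- gating_tables(c(40), model_params())
  expect_equal(gt2$hs_inf, 0.16, tolerance = 1e-4)
  expect_equal(gt2$b_inf, 0.12, tolerance = 1e-4)
  expect_equal(gt2$s_inf, model_params()$s_min, tolerance = 1e-4)
})

test_that("the integrator raises on a non-finite state rather than emitting garbage", {
  p <- model_params(E_na = NaN)
  proto <- make_protocol("cc_step", "mouse")
  expect_error(simulate_cc_sweep(p, proto, 100, seed = 1), "blow-up")
})
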