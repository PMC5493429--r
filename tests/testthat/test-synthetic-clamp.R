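test_that("noiseless generation reproduces the deterministic clamp exactly", {
  proto <- proto_act_small()
  spec <- clamp_data_spec(noise_sd = 0)
  gen <- generate_traces(spec, proto)
  ref <- simulate_voltage_clamp(ikur_model(), proto)
  expect_identical(gen$traces$current_pA_per_pF,
                   ref$traces$current_pA_per_pF)
})

test_that("generation is bit-reproducible per seed", {
  proto <- proto_act_small()
  spec <- clamp_data_spec(noise_sd = 0.5, seed = 42)
  a <- generate_traces(spec, proto)
  b <- generate_traces(spec, proto)
  expect_identical(a$traces$current_pA_per_pF, b$traces$current_pA_per_pF)
  spec2 <- clamp_data_spec(noise_sd = 0.5, seed = 43)
  c2 <- generate_traces(spec2, proto)
  expect_false(identical(a$traces$current_pA_per_pF,
                         c2$traces$current_pA_per_pF))
})

test_that("fast/slow mixture behaves as a weighted sum of kinetics", {
  proto <- clamp_protocol(step_voltages = 40, step_duration = 200)
  pure_fast <- generate_traces(
    clamp_data_spec(fast_slow = list(fast = 0.5, slow = 2, w = 1)), proto)
  fast_only <- local({
    m <- ikur_model(); m$tau_act_scale <- 0.5
    simulate_voltage_clamp(m, proto)
  })
  expect_equal(pure_fast$traces$current_pA_per_pF,
               fast_only$traces$current_pA_per_pF, tolerance = 1e-12)

  # fitted mono-exponential tau of a w-mixture lies between the pure taus
  tau_of <- function(w) {
    g <- generate_traces(
      clamp_data_spec(fast_slow = list(fast = 0.5, slow = 2, w = w)), proto,
      dt_sample = 0.2)
    fit_monoexp_tau(g$traces[g$traces$time_ms <= 30, ])
  }
  tau_fast <- tau_of(1); tau_slow <- tau_of(0)
  for (w in seq(0.1, 0.9, by = 0.2)) {
    tw <- tau_of(w)
    expect_gte(tw, tau_fast - 1e-9)
    expect_lte(tw, tau_slow + 1e-9)
  }
})

test_that("steady-state point extraction matches its contracts", {
  proto <- proto_act_small()
  gen <- generate_traces(clamp_data_spec(), proto)
  # raw (experiment-style) normalisation: maximal step point is 1
  pts_raw <- steady_state_points(gen, "activation", proto)
  expect_equal(max(pts_raw$fraction), 1)
  # truth-corrected points lie exactly on the activation curve
  pts <- steady_state_points(gen, "activation", proto, correction = "truth")
  expect_lt(max(abs(pts$fraction -
                      activation_steady_state(pts$v_mV, ikur_model()))),
            1e-6)
  # availability arm, truth-corrected, lies on the inactivation curve
  pav <- proto_avail_long()
  genav <- generate_traces(clamp_data_spec(), pav, mode = "availability")
  ipts <- steady_state_points(genav, "availability", pav,
                              correction = "truth")
  expect_lt(max(abs(ipts$fraction -
                      inactivation_steady_state(ipts$v_mV, ikur_model()))),
            1e-6)
})

test_that("noisy point-wise means converge to the noiseless curve", {
  proto <- clamp_protocol(step_voltages = seq(-40, 60, 20),
                          step_duration = 1500)
  noiseless <- steady_state_points(
    generate_traces(clamp_data_spec(), proto), "activation", proto,
    correction = "truth")
  reps <- sapply(1:50, function(s) {
    g <- generate_traces(clamp_data_spec(noise_sd = 2, seed = s), proto)
    steady_state_points(g, "activation", proto, correction = "truth",
                        truth = ikur_model())$fraction
  })
  expect_lt(max(abs(rowMeans(reps) - noiseless$fraction)), 0.05)
})

test_that("zero maximal current triggers the division guard", {
  proto <- clamp_protocol(step_voltages = c(-87, -87, -87, -87),
                          step_duration = 100)
  gen <- generate_traces(clamp_data_spec(), proto, e_k = -87)
  expect_error(steady_state_points(gen, "activation", proto, e_k = -87),
               "normalise")
})
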