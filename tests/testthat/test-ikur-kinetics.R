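test_that("WT steady states and time constants match their closed forms", {
  wt <- ikur_model()
  # activation: product of the two Boltzmann factors
  expect_equal(activation_steady_state(-17.67, wt),
               0.5 / (1 + exp((-17.67 + 8.45) / -11.51)), tolerance = 1e-12)
  expect_lt(activation_steady_state(-100, wt), 1e-6)
  expect_equal(activation_steady_state(80, wt), 0.99954, tolerance = 1e-4)
  # inactivation: floor (minimum availability), midpoint, ceiling
  expect_equal(inactivation_steady_state(1e7, wt), 0.46, tolerance = 1e-9)
  expect_equal(inactivation_steady_state(15.11, wt), 0.72, tolerance = 1e-12)
  expect_equal(inactivation_steady_state(-1e7, wt), 0.98, tolerance = 1e-9)
  # tau limits after Q10 division
  expect_equal(tau_activation(1e7, wt), 4.27 * 0.55 / 3.52,
               tolerance = 1e-9)
  expect_equal(tau_activation(-1e7, wt), 49.94 * 0.29 / 3.52,
               tolerance = 1e-9)
  expect_equal(tau_inactivation(1e7, wt), 1739.14 / 3.52, tolerance = 1e-9)
  expect_equal(tau_inactivation(-1e7, wt), (2328 + 1739.14) / 3.52,
               tolerance = 1e-9)
  # voltage-dependent maximal conductance plateaus
  expect_equal(conductance_scale(-1e7, wt), 0.64 * 4.51, tolerance = 1e-9)
  expect_equal(conductance_scale(1e7, wt), 0.64 * 6.41, tolerance = 1e-9)
})

test_that("Q10 correction is an exact scalar division", {
  wt <- ikur_model()
  raw <- wt
  raw$kq10 <- 1
  v <- seq(-100, 80, by = 7)
  expect_equal(tau_activation(v, raw), 3.52 * tau_activation(v, wt),
               tolerance = 1e-12)
  expect_equal(tau_inactivation(v, raw), 3.52 * tau_inactivation(v, wt),
               tolerance = 1e-12)
})

test_that("steady states are bounded and time constants positive on the grid", {
  v <- seq(-100, 80, by = 1)
  for (label in c("WT", kcna5_variants()$mutation)) {
    m <- if (label == "WT") ikur_model() else apply_mutant(label)
    a <- activation_steady_state(v, m)
    i <- inactivation_steady_state(v, m)
    expect_true(all(a >= 0 & a <= 1), label = paste(label, "activation"))
    expect_true(all(i >= 0 & i <= 1), label = paste(label, "inactivation"))
    expect_true(all(tau_activation(v, m) > 0))
    expect_true(all(tau_inactivation(v, m) > 0))
  }
  # tau_inactivation decreases monotonically with voltage
  expect_true(all(diff(tau_inactivation(v, ikur_model())) <= 0))
})

test_that("variant construction applies the WT-relative changes", {
  wt_eq <- wt_equivalent_activation()
  d469e <- apply_mutant("D469E")
  expect_equal(d469e$act_ss[[1]]$v_half, wt_eq$v_half)  # dV1/2 = 0
  expect_equal(d469e$act_ss[[1]]$slope_k, wt_eq$slope_k)
  expect_equal(d469e$inact_ss$v_half, 15.11 + 4.545)
  expect_equal(d469e$inact_ss$slope_k, 7.57 * 0.842)
  expect_equal(d469e$inact_ss$floor_ma, 0.46 - 0.093)
  expect_equal(d469e$g_factor, 0.546)
  # conductance scales multiplicatively at every voltage
  y155c <- apply_mutant("Y155C")
  v <- c(-40, 0, 40)
  expect_equal(conductance_scale(v, y155c),
               0.475 * conductance_scale(v, ikur_model()))
  p488s <- apply_mutant("P488S")
  expect_equal(conductance_scale(10, p488s),
               0.038 * conductance_scale(10, ikur_model()))
  # identity delta reproduces the WT-equivalent model
  ident <- apply_mutant(mutant_delta())
  expect_equal(ident$act_ss[[1]], wt_eq)
  expect_equal(ident$inact_ss, ikur_model()$inact_ss)
  expect_equal(ident$g_factor, 1)
  # tau parameters always copied from WT
  expect_identical(d469e$tau_act_params, ikur_model()$tau_act_params)
  expect_identical(d469e$tau_inact_params, ikur_model()$tau_inact_params)
  # invalid deltas rejected
  expect_error(mutant_delta(k_act_factor = 0), "positive")
  expect_error(mutant_delta(g_factor = -1), "non-negative")
  # alias for the mutant named inconsistently in the literature
  expect_equal(variant_delta("D322H"), variant_delta("D332H"))
})

test_that("current composition and trivial zeros hold", {
  wt <- ikur_model()
  expect_equal(ikur_current(30, 0, 0.7, -85, wt), 0)
  expect_equal(ikur_current(-85, 0.5, 0.7, -85, wt), 0)
  a <- activation_steady_state(30, wt)
  i <- inactivation_steady_state(30, wt)
  expect_equal(ikur_current(30, a, i, -85, wt),
               conductance_scale(30, wt) * a * i * 115)
})

test_that("Rush-Larsen gate update matches a fine-step Euler oracle", {
  wt <- ikur_model()
  for (v in c(-60, -20, 20, 50)) {
    state <- c(0.1, 0.9)
    dt <- 5
    rl <- step_gates(state, v, dt, wt)
    # independent oracle: fine-step explicit Euler (step small enough that
    # its own truncation error on the fastest gate sits below the bound)
    n <- 200000
    h <- dt / n
    ai <- state
    a_inf <- activation_steady_state(v, wt)
    i_inf <- inactivation_steady_state(v, wt)
    ta <- tau_activation(v, wt)
    ti <- tau_inactivation(v, wt)
    for (k in seq_len(n))
      ai <- ai + h * c((a_inf - ai[1]) / ta, (i_inf - ai[2]) / ti)
    expect_lt(max(abs(rl - ai)), 1e-6)
  }
  # dt = 0 leaves the state unchanged; dt -> infinity reaches steady state
  expect_equal(step_gates(c(0.3, 0.5), 10, 0, wt), c(0.3, 0.5))
  expect_equal(step_gates(c(0.3, 0.5), 10, 1e9, wt),
               c(activation_steady_state(10, wt),
                 inactivation_steady_state(10, wt)))
})

test_that("simulated voltage clamp composes with the steady-state forms", {
  wt <- ikur_model()
  # step to E_K gives a flat zero trace
  pz <- clamp_protocol(step_voltages = -87, step_duration = 100)
  rz <- simulate_voltage_clamp(wt, pz, e_k = -87)
  expect_lt(max(abs(rz$traces$current_pA_per_pF)), 1e-12)
  # long steps end at the closed-form steady-state current
  pl <- clamp_protocol(step_voltages = c(-20, 0, 40),
                       step_duration = 30000)
  rl <- simulate_voltage_clamp(wt, pl, e_k = -87)
  for (v in pl$step_voltages) {
    iv <- rl$iv$current_pA_per_pF[rl$iv$step_v_mV == v]
    expect_equal(iv, ikur_current(v, activation_steady_state(v, wt),
                                  inactivation_steady_state(v, wt), -87, wt),
                 tolerance = 1e-4)
  }
  # WT end-pulse I-V is monotone non-decreasing from -40 to +60 mV
  piv <- clamp_protocol(step_voltages = seq(-40, 60, 10),
                        step_duration = 1500)
  riv <- simulate_voltage_clamp(wt, piv, e_k = -87)
  expect_true(all(diff(riv$iv$current_pA_per_pF) >= 0))
})
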