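test_that("Boltzmann fits recover exact synthetic parameters", {
  v <- seq(-60, 40, by = 5)
  pts <- tibble::tibble(v_mV = v,
                        fraction = boltzmann(v, boltzmann_params(-10, -6)))
  fit <- fit_boltzmann_activation(pts)
  expect_lt(abs(fit$params$v_half - -10), 1e-6)
  expect_lt(abs(fit$params$slope_k - -6), 1e-6)
  expect_lt(fit$rss, 1e-12)

  # inactivation: the unnormalised WT availability curve
  vi <- seq(-100, 60, by = 10)
  ipts <- tibble::tibble(v_mV = vi,
                         fraction = inactivation_steady_state(vi,
                                                              ikur_model()))
  ifit <- fit_boltzmann_inactivation(ipts, normalised = FALSE)
  expect_lt(abs(ifit$params$v_half - 15.11), 1e-6)
  expect_lt(abs(ifit$params$slope_k - 7.57), 1e-6)
  expect_lt(abs(ifit$params$floor_ma - 0.46), 1e-6)
  expect_lt(abs(ifit$params$amplitude - 0.52), 1e-6)

  # tidy/glance expose the estimates
  td <- tidy(ifit)
  expect_equal(td$estimate[td$term == "floor_ma"], ifit$params$floor_ma)
  expect_true(glance(ifit)$converged)
})

test_that("WT-equivalent activation fit agrees with a grid-search oracle", {
  eq <- wt_equivalent_activation()
  v <- seq(-60, 60, by = 1)
  y <- activation_steady_state(v, ikur_model())
  sse <- function(vh, k) sum((y - 1 / (1 + exp((v - vh) / k)))^2)
  grid <- expand.grid(vh = seq(-10, 0, 0.25), k = seq(-12, -5, 0.25))
  best <- grid[which.min(mapply(sse, grid$vh, grid$k)), ]
  expect_lt(abs(eq$v_half - best$vh), 0.25)
  expect_lt(abs(eq$slope_k - best$k), 0.25)
  # and the fit cannot be worse than the oracle's grid optimum
  expect_lte(sse(eq$v_half, eq$slope_k), sse(best$vh, best$k) + 1e-12)
})

test_that("flat availability data yields the floor with a warning", {
  pts <- tibble::tibble(v_mV = seq(-80, 40, 20), fraction = 0.37)
  expect_warning(fit <- fit_boltzmann_inactivation(pts), "unidentifiable")
  expect_equal(fit$params$floor_ma, 0.37, tolerance = 1e-9)
  expect_lt(fit$params$amplitude, 1e-6)
  expect_true("v_half" %in% fit$unidentifiable)
})

test_that("mono-exponential tau fitting recovers known kinetics", {
  # exact synthetic exponential
  t <- seq(0, 100, 0.5)
  tr <- tibble::tibble(time_ms = t,
                       current_pA_per_pF = 5 * (1 - exp(-t / 12)) + 1)
  expect_lt(abs(fit_monoexp_tau(tr, window = c(0, 100)) - 12), 1e-6)
  # decay direction
  trd <- tibble::tibble(time_ms = t,
                        current_pA_per_pF = 4 * exp(-t / 7) + 0.5)
  expect_lt(abs(fit_monoexp_tau(trd, window = c(0, 100)) - 7), 1e-6)
  # non-monotone window rejected
  trb <- tibble::tibble(time_ms = t, current_pA_per_pF = sin(t / 5))
  expect_error(fit_monoexp_tau(trb, window = c(0, 100)), "monotone")

  # clamp trace at +40 mV with inactivation frozen: the activation phase is
  # exactly exponential in the gate, so the fitted tau matches tau_a
  frozen <- ikur_model()
  frozen$inact_ss <- boltzmann_params(0, 10, amplitude = 1e-9,
                                      floor_ma = 1 - 1e-9)
  proto <- clamp_protocol(step_voltages = 40, step_duration = 60)
  g <- simulate_voltage_clamp(frozen, proto, dt_sample = 0.1)
  tau_hat <- fit_monoexp_tau(g$traces)
  expect_lt(abs(tau_hat - tau_activation(40, frozen)) /
              tau_activation(40, frozen), 0.02)
})

test_that("Q10 application is exact division with guards", {
  expect_equal(apply_q10(3.52, 3.52), 1)
  expect_equal(apply_q10(49.94 * 0.29, 3.52), 4.114, tolerance = 1e-3)
  expect_equal(apply_q10(7.5, 1), 7.5)
  expect_error(apply_q10(-1, 3.52))
})

test_that("relative-change derivation inverts variant construction", {
  wt <- fit_channel_variant("WT")
  # identical fits give the identity delta
  ident <- derive_relative_changes(wt, wt)
  expect_equal(unlist(ident),
               unlist(mutant_delta()), tolerance = 1e-12)
  # generate-fit-difference round trip for one variant
  mf <- fit_channel_variant("D469E")
  d <- derive_relative_changes(wt, mf)
  expect_lt(max(abs(unlist(d) - unlist(variant_delta("D469E")))), 1e-9)
})

test_that("fitting is invariant to grid permutation and current rescaling", {
  proto <- proto_act_small()
  gen <- generate_traces(clamp_data_spec(noise_sd = 1, seed = 7), proto)
  pts <- steady_state_points(gen, "activation", proto)
  fit1 <- fit_boltzmann_activation(pts)
  # permute the voltage grid
  perm <- pts[sample.int(nrow(pts)), ]
  fit2 <- fit_boltzmann_activation(perm)
  expect_equal(fit1$params$v_half, fit2$params$v_half, tolerance = 1e-6)
  # uniformly rescale the raw currents: normalised points are unchanged
  gen2 <- gen
  gen2$traces$current_pA_per_pF <- 3.7 * gen2$traces$current_pA_per_pF
  pts2 <- steady_state_points(gen2, "activation", proto)
  expect_equal(pts$fraction, pts2$fraction, tolerance = 1e-12)
})

test_that("parameter recovery degrades monotonically with noise", {
  proto <- clamp_protocol(step_voltages = seq(-50, 60, 10),
                          step_duration = 1500)
  plateau <- max(abs(simulate_voltage_clamp(ikur_model(),
                                            proto)$iv$current_pA_per_pF))
  mae <- sapply(c(0, 0.01, 0.05, 0.10) * plateau, function(sd) {
    errs <- sapply(1:50, function(s) {
      g <- generate_traces(clamp_data_spec(noise_sd = sd, seed = s), proto)
      pts <- steady_state_points(g, "activation", proto,
                                 correction = "truth",
                                 truth = ikur_model())
      fit <- tryCatch(fit_boltzmann_activation(pts),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      abs(fit$params$v_half - wt_equivalent_activation()$v_half)
    })
    mean(errs, na.rm = TRUE)
  })
  expect_true(all(diff(mae) >= -0.05 * max(mae)))
  # 5% noise still recovers the half-activation voltage to ~1 mV
  expect_lt(mae[3], 1.5)
})
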