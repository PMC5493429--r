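test_that("cell construction validates its inputs and variants", {
  expect_error(build_cell("courtemanche", mutation = "Q999X"),
               "unknown mutation")
  # identity mutation is exactly the WT parameterisation
  wt <- build_cell("courtemanche_newIKur", mutation = "WT")
  ident <- build_cell("courtemanche_newIKur", mutation = "WT")
  expect_identical(wt$params, ident$params)
  # CT carries a larger L-type Ca conductance than PM in both lineages
  g_ct <- build_cell("grandi", region = "CT")
  g_pm <- build_cell("grandi", region = "PM")
  expect_gt(g_ct$params[5], g_pm$params[5])
  c_ct <- build_cell("courtemanche", region = "CT")
  c_pm <- build_cell("courtemanche", region = "PM")
  expect_gt(c_ct$params[3], c_pm$params[3])
})

test_that("paced APD90 agrees with an independent stiff-solver oracle", {
  skip_if_not_installed("deSolve")
  cell <- build_cell("courtemanche")
  tr <- pace(cell, pacing_protocol(n_s1 = 5, s1_cl = 1000), dt = 0.005)
  ap <- measure_ap(tr, beat = 5)
  orc <- ctm_oracle_trace(n_beats = 5)
  attr(orc, "stim_times") <- attr(tr, "stim_times")
  ap_o <- measure_ap(orc, beat = 5)
  expect_lt(abs(ap$apd90 - ap_o$apd90) / ap_o$apd90, 0.05)
  expect_lt(abs(ap$rmp - ap_o$rmp), 2)
})

test_that("unstimulated cells rest stably for 10 s", {
  for (id in c("courtemanche", "grandi")) {
    cell <- build_cell(id)
    tr <- pace(cell, pacing_protocol(n_s1 = 1, s1_cl = 10000,
                                     stim_amplitude = 0))
    tail_v <- tr$v_mV[tr$time_ms >= 9000]
    dvdt <- abs(diff(tail_v)) / 0.5
    expect_lt(max(dvdt), 0.01, label = paste(id, "resting dV/dt"))
  }
})

test_that("pacing is deterministic and convergent in dt", {
  cell <- build_cell("courtemanche_newIKur")
  a <- pace(cell, pacing_protocol(n_s1 = 2))
  b <- pace(cell, pacing_protocol(n_s1 = 2))
  expect_identical(a$v_mV, b$v_mV)
  # halving the step changes APD90 by < 1 ms
  for (id in c("courtemanche", "grandi")) {
    c2 <- build_cell(id)
    t1 <- pace(c2, pacing_protocol(n_s1 = 3), dt = default_dt(c2$code))
    t2 <- pace(c2, pacing_protocol(n_s1 = 3), dt = default_dt(c2$code) / 2)
    expect_lt(abs(measure_ap(t1, 3)$apd90 - measure_ap(t2, 3)$apd90), 1,
              label = paste(id, "dt convergence"))
  }
})

test_that("AP metrics match closed-form geometry on a synthetic trapezoid", {
  tr <- trapezoid_trace(rest = -80, peak = 20, repol_ms = 300)
  ap <- measure_ap(tr, beat = 1)
  # linear repolarisation from +20 at t=12: V90 = -70 reached at t = 282
  up <- 10 + 2 * (20 - -40) / (20 - -80)  # -40 mV crossing on the upstroke
  expect_lt(abs(ap$apd90 - (12 + 0.9 * 300 - up)), 1)
  expect_lt(abs(ap$apd30 - (12 + 0.3 * 300 - up)), 1)
  expect_equal(ap$peak_v, 20, tolerance = 0.5)
  expect_equal(ap$ead_count, 0)
  # a trace that never crosses -40 mV has no upstroke
  flat <- tibble::tibble(time_ms = seq(0, 100, 0.5), v_mV = -80)
  attr(flat, "stim_times") <- 10
  expect_error(measure_ap(flat, 1), "no upstroke")
})

test_that("EAD detection counts plateau re-depolarisations only", {
  tr <- trapezoid_trace()
  expect_equal(detect_eads(tr, 1), 0)
  # inject a 10 mV bump during the plateau (the -40 mV crossing of the
  # trapezoid sits at ~192 ms, so bumps must come earlier)
  bump <- tr
  sel <- bump$time_ms >= 60 & bump$time_ms <= 100
  bump$v_mV[sel] <- bump$v_mV[sel] +
    10 * sin(pi * (bump$time_ms[sel] - 60) / 40)^2
  expect_equal(detect_eads(bump, 1, skip_dome = FALSE), 1)
  # two bumps: the first is treated as the dome unless skip_dome = FALSE
  bump2 <- bump
  sel2 <- bump2$time_ms >= 130 & bump2$time_ms <= 170
  bump2$v_mV[sel2] <- bump2$v_mV[sel2] +
    10 * sin(pi * (bump2$time_ms[sel2] - 130) / 40)^2
  expect_equal(detect_eads(bump2, 1, skip_dome = FALSE), 2)
  expect_equal(detect_eads(bump2, 1), 1)
})

test_that("APD30 never exceeds APD90 across model variants", {
  for (id in c("courtemanche", "courtemanche_newIKur", "grandi")) {
    for (mut in c("WT", "D332H", "P488S")) {
      cell <- build_cell(id, mutation = mut)
      tr <- pace(cell, pacing_protocol(n_s1 = 2))
      ap <- measure_ap(tr, 2)
      expect_lte(ap$apd30, ap$apd90,
                 label = paste(id, mut, "APD30 <= APD90"))
    }
  }
})

test_that("P488S nearly abolishes I_Kur relative to WT during an AP", {
  # drive both channel variants with the same AP voltage waveform and
  # compare peak currents; conductance x0.038 dominates
  wt <- ikur_model()
  p488s <- apply_mutant("P488S")
  tr <- pace(build_cell("courtemanche_newIKur"), pacing_protocol(n_s1 = 2))
  w <- tr[tr$time_ms >= 1010 & tr$time_ms <= 1400, ]
  gates <- function(model) {
    a <- activation_steady_state(w$v_mV[1], model)
    i <- inactivation_steady_state(w$v_mV[1], model)
    out <- numeric(nrow(w))
    for (k in seq_len(nrow(w))) {
      g <- step_gates(c(a, i), w$v_mV[k], 0.5, model)
      a <- g[1]; i <- g[2]
      out[k] <- ikur_current(w$v_mV[k], a, i, -85, model)
    }
    out
  }
  expect_lt(max(gates(p488s)) / max(gates(wt)), 0.05)
})

test_that("restitution returns the steady APD at s2 = s1_cl and flags loss of capture", {
  cell <- build_cell("courtemanche_newIKur")
  rc <- restitution(cell, s2_grid = c(50, 500, 800, 1000), n_s1 = 20,
                    s1_cl = 1000)
  steady <- measure_ap(pace(precondition(cell, 20, 1000),
                            pacing_protocol(n_s1 = 1)), 1)
  s2eq <- rc$apd90[rc$s2 == 1000]
  expect_true(rc$captured[rc$s2 == 1000])
  expect_lt(abs(s2eq - steady$apd90), 2)
  # very short coupling fails to capture and is flagged, not dropped
  expect_false(rc$captured[rc$s2 == 50])
  expect_true(all(c(50, 500, 800, 1000) %in% rc$s2))
  # APD90 monotone non-decreasing over captured s2 >= 400 ms
  cap <- rc[rc$captured & rc$s2 >= 400, ]
  expect_true(all(diff(cap$apd90) >= -1e-9))
})
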