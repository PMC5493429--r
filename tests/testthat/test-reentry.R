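test_that("dominant frequency analysis matches known signals", {
  t <- seq(0, 5000, by = 1)
  # pure 6 Hz sinusoid, resolution 1/window = 0.2 Hz
  v <- 10 * sin(2 * pi * 6 * t / 1000)
  expect_lt(abs(dominant_frequency(v, t) - 6), 0.2 + 1e-9)
  # periodic 2 Hz pulse train (paced-cell surrogate)
  v2 <- ifelse((t %% 500) < 150, 20, -80)
  expect_lt(abs(dominant_frequency(v2, t) - 2), 0.2 + 1e-9)
  # quiescent trace reports 0 Hz
  expect_equal(dominant_frequency(rep(-80, length(t)), t), 0)
  # a 5 s window resolves frequencies on a 0.2 Hz grid
  f <- dominant_frequency(10 * sin(2 * pi * 6.1 * t / 1000), t)
  expect_lt(abs(f - 6.1), 0.2 + 1e-9)
})

test_that("a paced cell's dominant frequency equals its pacing rate", {
  cell <- precondition(build_cell("courtemanche", caf = TRUE),
                       n_beats = 10, cl = 500)
  tr <- pace(cell, pacing_protocol(n_s1 = 6, s1_cl = 500))
  expect_lt(abs(dominant_frequency(tr$v_mV, tr$time_ms, window = 3000) - 2),
            1 / 3 + 1e-9)
})

test_that("phase libraries span the AP cycle and reject degenerate sizes", {
  cell <- build_cell("courtemanche", caf = TRUE)
  expect_error(build_phase_library(cell, n_snapshots = 1), "degenerate")
  lib <- build_phase_library(cell, cycle_length = 500, n_snapshots = 32,
                             n_beats = 12)
  vs <- vapply(lib$states, function(s) s[1], numeric(1))
  # snapshots cover diastole to the plateau (the narrow spike peak can fall
  # between two snapshot times)
  expect_lt(min(vs), -70)
  expect_gt(max(vs), -20)
  # periodicity: the first and last snapshots both sit in diastole
  expect_lt(abs(vs[1] - vs[32]), 25)
})

test_that("uniform-phase sheets stay quiet and mirrored layouts mirror", {
  cell <- precondition(build_cell("courtemanche", caf = TRUE),
                       n_beats = 10, cl = 500)
  lib <- build_phase_library(cell, cycle_length = 500, n_snapshots = 32,
                             n_beats = 4)
  sheet <- sheet_config(cell, nx = 60, ny = 60, dx = 0.33, D_base = 0.1,
                        d_scale = 0.4)
  # uniform phase: no propagating wave develops
  uni <- init_sheet_phase_map(sheet, lib, layout = "uniform")
  rm_u <- run_reentry(sheet, uni, duration = 400, dt = 0.02,
                      df_window = 400)
  expect_false(attr(rm_u, "sustained"))
  expect_lt(attr(rm_u, "lifetime"), 400)
  # mirrored archimedean layouts give mirrored voltage fields
  a <- init_sheet_phase_map(sheet, lib, layout = "archimedean")
  b <- init_sheet_phase_map(sheet, lib, layout = "archimedean",
                            mirror = TRUE)
  ra <- run_reentry(sheet, a, duration = 150, dt = 0.02, df_window = 150,
                    field_times = 140)
  rb <- run_reentry(sheet, b, duration = 150, dt = 0.02, df_window = 150,
                    field_times = 140)
  fa <- matrix(attr(ra, "fields")[[1]], 60, 60)
  fb <- matrix(attr(rb, "fields")[[1]], 60, 60)
  expect_lt(max(abs(fa - fb[, 60:1])), 1e-6)
})

test_that("an archimedean phase map seeds a rotating wave", {
  cell <- precondition(build_cell("courtemanche", caf = TRUE),
                       n_beats = 10, cl = 500)
  lib <- build_phase_library(cell, cycle_length = 500, n_snapshots = 48,
                             n_beats = 4)
  sheet <- sheet_config(cell, nx = 120, ny = 120, dx = 0.33, D_base = 0.1,
                        d_scale = 0.4)
  init <- init_sheet_phase_map(sheet, lib, layout = "archimedean")
  rm <- run_reentry(sheet, init, duration = 700, dt = 0.02, n_sites = 3,
                    df_window = 700)
  # re-entrant activity outlives any single AP: activations continue well
  # past the initial wave and at least one site is re-excited repeatedly
  expect_gt(attr(rm, "lifetime"), 500)
  tr <- attr(rm, "site_traces"); t <- attr(rm, "time")
  n_act <- apply(tr, 2, function(v)
    sum(v >= -40 & c(-Inf, v[-length(v)]) < -40))
  expect_gte(max(n_act), 2)
})
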