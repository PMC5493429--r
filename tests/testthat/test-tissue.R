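test_that("uncoupled nodes evolve exactly like the isolated cell", {
  cell <- build_cell("courtemanche_newIKur")
  cfg <- cable_config(cell, n_nodes = 50, dx = 0.25, D = 0)
  run <- solve_cable(cfg,
                     data.frame(onset = 10, duration = 2, amplitude = 25,
                                node_lo = 1, node_hi = 1),
                     duration = 500, record_dt = 0.5)
  # stimulus at node 1 only: no activation spreads with D = 0
  at <- activation_times(run)
  expect_false(is.na(at[1]))
  expect_true(all(is.na(at[-1])))
  # the stimulated node's trace is bit-identical to the single cell's
  single <- pace(cell, pacing_protocol(n_s1 = 1, s1_cl = 490),
                 dt = default_dt(cell$code), record_dt = 0.5)
  n <- nrow(run$v)
  expect_identical(run$v[, 1], single$v_mV[seq_len(n)])
  # unstimulated nodes match the quiescent cell to machine precision
  quiet <- pace(cell, pacing_protocol(n_s1 = 1, s1_cl = 490,
                                      stim_amplitude = 0),
                record_dt = 0.5)
  expect_lt(max(abs(run$v[, 25] - quiet$v_mV[seq_len(n)])), 1e-9)
})

test_that("midpoint stimulation of a uniform strand is symmetric", {
  cell <- build_cell("courtemanche_newIKur")
  cfg <- cable_config(cell, n_nodes = 101, dx = 0.25, D = 0.3)
  init <- cable_init_state(cfg, precondition_beats = 20)
  run <- solve_cable(cfg,
                     data.frame(onset = 5, duration = 2, amplitude = 30,
                                node_lo = 49, node_hi = 53),
                     duration = 120, record_dt = 0.25, init_state = init)
  at <- activation_times(run)
  k <- 35
  expect_lt(max(abs((at[51 - k:1] - at[51]) - (at[51 + k:1] - at[51]))),
            0.25 + 1e-9)
})

test_that("conduction velocity measurement matches synthetic kinematics", {
  # linear activation ramp of 1 ms per mm -> 1 m/s
  n <- 100; dx <- 0.25
  t <- seq(0, 60, by = 0.25)
  v <- sapply(seq_len(n), function(i) {
    ifelse(t >= (i - 1) * dx * 1, 20, -80)  # 1 ms per mm
  })
  st <- structure(list(time = t, v = v,
                       config = list(dx = dx, n_nodes = n)),
                  class = "cable_spacetime")
  expect_equal(measure_cv(st), 1.0, tolerance = 1e-6)
  # a blocked wave raises an error rather than returning a number
  v2 <- v; v2[, 60:100] <- -80
  st2 <- structure(list(time = t, v = v2,
                        config = list(dx = dx, n_nodes = n)),
                   class = "cable_spacetime")
  expect_error(measure_cv(st2), "block")
})

test_that("conduction velocity scales as the square root of diffusion", {
  cell <- build_cell("courtemanche_newIKur")
  cfg <- cable_config(cell, n_nodes = 150, dx = 0.25, D = 0.4)
  init <- cable_init_state(cfg, precondition_beats = 20)
  cv_at <- function(D) {
    cfg$d_profile <- rep(D, cfg$n_nodes)
    run <- solve_cable(cfg,
                       data.frame(onset = 5, duration = 2, amplitude = 30,
                                  node_lo = 1, node_hi = 8),
                       duration = 250, record_dt = 0.25, init_state = init)
    measure_cv(run)
  }
  expect_lt(abs(cv_at(0.4) / cv_at(0.1) - 2) / 2, 0.10)
})

test_that("spatial refinement changes the measured CV only modestly", {
  cell <- build_cell("courtemanche_newIKur")
  cv_dx <- function(dx, n) {
    cfg <- cable_config(cell, n_nodes = n, dx = dx, D = 0.3)
    init <- cable_init_state(cfg, precondition_beats = 20)
    run <- solve_cable(cfg,
                       data.frame(onset = 5, duration = 2, amplitude = 30,
                                  node_lo = 1, node_hi = round(2 / dx)),
                       duration = 120, record_dt = 0.25,
                       init_state = init, dt = 0.005)
    measure_cv(run)
  }
  # measured discretisation sensitivity at the default 0.25 mm spacing is
  # ~5%; CV comparisons in the package therefore always share one spacing
  expect_lt(abs(cv_dx(0.25, 100) - cv_dx(0.125, 200)) / cv_dx(0.125, 200),
            0.06)
})

test_that("homogeneous strands never produce unidirectional block", {
  cell <- build_cell("courtemanche_newIKur")
  cfg <- cable_config(cell, n_nodes = 100, dx = 0.25, D = 0.3)
  prep <- s1s2_prepare(cfg, n_s1 = 3, s1_cl = 500,
                       precondition_beats = 20)
  outs <- dplyr::bind_rows(lapply(c(150, 250, 350, 500),
                                  function(s2) s1s2_outcome(prep, s2)))
  expect_false(any(grepl("unidirectional", outs$outcome)))
  # short coupling blocks both ways, long coupling conducts both ways
  expect_equal(outs$outcome[1], "bidirectional_block")
  expect_equal(outs$outcome[4], "bidirectional_conduction")
  # and the scanned window has width zero
  vw <- vulnerability_window(prep, scan = c(150, 500), coarse = 50)
  expect_equal(vw$width, 0)
})
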