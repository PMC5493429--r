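# Shared fixtures and caches for the test suite.  Everything here is built
# in code at test time; expensive intermediates (calibrations, preconditioned
# states) are computed once per session.

.test_cache <- new.env(parent = emptyenv())

cache_once <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# small clamp protocols used across fitting tests
proto_act_small <- function() {
  clamp_protocol(step_voltages = seq(-60, 60, 10), step_duration = 1500)
}
proto_avail_long <- function() {
  clamp_protocol(step_voltages = seq(-100, 60, 10), step_duration = 30000)
}

# calibrated strand shared by the conduction-velocity criteria
cv_calibration <- function() {
  cache_once("cv_cal", {
    cell <- build_cell("courtemanche_newIKur")
    cfg <- cable_config(cell, n_nodes = 200, dx = 0.25)
    cal <- calibrate_diffusion(cfg, target_cv = 1.3, tolerance = 0.01)
    list(cfg = cfg, cal = cal)
  })
}

# synthetic trapezoidal AP with known geometry, as a pace()-like tibble
trapezoid_trace <- function(rest = -80, peak = 20, repol_ms = 300,
                            dt = 0.5) {
  t <- seq(0, 600, by = dt)
  v <- rep(rest, length(t))
  up <- t >= 10 & t < 12
  v[up] <- rest + (t[up] - 10) / 2 * (peak - rest)
  plateau <- t >= 12 & t < 12 + repol_ms
  v[plateau] <- peak - (t[plateau] - 12) / repol_ms * (peak - rest)
  out <- tibble::tibble(time_ms = t, v_mV = v)
  attr(out, "stim_times") <- 10
  out
}
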