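#' 1D cable (strand) configuration
#'
#' A monodomain strand of coupled atrial cells with a per-node diffusion
#' profile and per-node region labels.  Heterogeneous strands (e.g. half
#' crista terminalis, half pectinate muscle) are built by giving one cell
#' template per label.
#'
#' @param cells A single [build_cell()] object, or a named list of them
#'   (names are the region labels).
#' @param n_nodes Number of nodes (>= 50).
#' @param dx Node spacing, mm (0.1 to 0.5).
#' @param D Scalar diffusion coefficient, mm^2/ms (used for every node
#'   unless `d_profile` is given).
#' @param region_labels Character vector of length `n_nodes` assigning each
#'   node a label from `names(cells)`; defaults to a contiguous equal split
#'   in list order.
#' @param d_profile Optional per-node diffusion coefficients, mm^2/ms.
#' @return An object of class `cable_config`.
#' @examples
#' cfg <- cable_config(build_cell("courtemanche"), n_nodes = 60, D = 0.1)
#' @export
cable_config <- function(cells, n_nodes = 200, dx = 0.25, D = 0.1,
                         region_labels = NULL, d_profile = NULL) {
  if (inherits(cells, "cell_instance")) cells <- list(strand = cells)
  stopifnot(length(cells) >= 1, all(vapply(cells, inherits, TRUE,
                                           "cell_instance")))
  if (n_nodes < 50) stop("n_nodes must be at least 50")
  if (dx < 0.1 || dx > 0.5) stop("dx must be in [0.1, 0.5] mm")
  codes <- vapply(cells, function(c) c$code, integer(1))
  if (length(unique(codes)) != 1)
    stop("all cells in a cable must share one model lineage")
  if (is.null(region_labels)) {
    k <- length(cells)
    region_labels <- rep(names(cells),
                         times = diff(round(seq(0, n_nodes, length.out = k + 1))))
  }
  stopifnot(length(region_labels) == n_nodes,
            all(region_labels %in% names(cells)))
  if (is.null(d_profile)) d_profile <- rep(D, n_nodes)
  stopifnot(length(d_profile) == n_nodes, all(d_profile >= 0))
  structure(
    list(cells = cells, n_nodes = n_nodes, dx = dx,
         region_labels = region_labels, d_profile = d_profile,
         code = codes[[1]]),
    class = "cable_config"
  )
}

#' @export
print.cable_config <- function(x, ...) {
  cat(sprintf("<cable_config> %d nodes x %.2f mm (%.1f mm), regions: %s\n",
              x$n_nodes, x$dx, x$n_nodes * x$dx,
              paste(unique(x$region_labels), collapse = "/")))
  invisible(x)
}

#' Half-CT / half-PM heterogeneous strand
#'
#' The junction geometry used for vulnerability-window protocols: the left
#' half of the strand is crista terminalis, the right half pectinate muscle.
#'
#' @inheritParams build_cell
#' @inheritParams cable_config
#' @export
ctpm_strand <- function(model_id = "grandi", mutation = "WT", caf = FALSE,
                        iso = FALSE, n_nodes = 200, dx = 0.25, D = 0.1) {
  cable_config(
    list(CT = build_cell(model_id, "CT", mutation, caf, iso),
         PM = build_cell(model_id, "PM", mutation, caf, iso)),
    n_nodes = n_nodes, dx = dx, D = D
  )
}

cable_param_sets <- function(config) {
  lapply(config$cells, function(c) c$params)
}

cable_node_set <- function(config) {
  match(config$region_labels, names(config$cells)) - 1L
}

#' Build an initial state matrix for a cable
#'
#' Each node starts from its region's cell state; optionally each region
#' template is first preconditioned in isolation by 1 Hz pacing.
#'
#' @param config A [cable_config()].
#' @param precondition_beats Single-cell conditioning beats per region
#'   template (0 = use the template states as they are).
#' @param cl Conditioning cycle length, ms.
#' @param dt Integration step, ms.
#' @param acute_iso Precondition with the isoprenaline set switched off
#'   (acute wash-in: the strand then runs with ISO from an ISO-free steady
#'   state).
#' @return A state matrix (n_state x n_nodes).
#' @export
cable_init_state <- function(config, precondition_beats = 0, cl = 1000,
                             dt = default_dt(config$code),
                             acute_iso = FALSE) {
  cells <- config$cells
  if (acute_iso)
    cells <- lapply(cells, function(c)
      build_cell(c$model_id, c$region, c$mutation, c$caf, iso = FALSE))
  if (precondition_beats > 0)
    cells <- lapply(cells, precondition, n_beats = precondition_beats,
                    cl = cl, dt = dt)
  states <- vapply(cells, function(c) c$state,
                   numeric(length(cells[[1]]$state)))
  states[, match(config$region_labels, names(cells)), drop = FALSE]
}

#' Solve the monodomain equation on a 1D strand
#'
#' Explicit finite differences with harmonic-mean face diffusion
#' coefficients and no-flux (mirrored ghost node) boundaries; cell dynamics
#' advance with Rush-Larsen/Euler steps at the same dt.  With D = 0 every
#' node evolves exactly as the isolated single cell.
#'
#' @param config A [cable_config()].
#' @param stimuli A data frame with columns `onset` (ms), `duration` (ms),
#'   `amplitude` (pA/pF), `node_lo`, `node_hi` (1-based, inclusive).
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms; must satisfy the diffusion stability
#'   bound dt <= dx^2 / (2 max D).
#' @param record_dt Sampling interval of the returned space-time record, ms.
#' @param init_state Initial state matrix (see [cable_init_state()]), or
#'   `NULL` for the per-region template states.
#' @param snapshot_times Times at which to keep full state snapshots, ms.
#' @return A `cable_spacetime` object: list with `time`, `v` (time x node
#'   matrix), `config`, `final_state`, `snapshots`.
#' @export
solve_cable <- function(config, stimuli, duration,
                        dt = default_dt(config$code), record_dt = 0.5,
                        init_state = NULL, snapshot_times = numeric(0)) {
  stopifnot(inherits(config, "cable_config"))
  maxd <- max(config$d_profile)
  if (maxd > 0 && dt > config$dx^2 / (2 * maxd))
    stop(sprintf("dt = %g violates the stability bound dx^2/(2 max D) = %g",
                 dt, config$dx^2 / (2 * maxd)))
  if (is.null(init_state)) init_state <- cable_init_state(config)
  stim <- as.matrix(as.data.frame(stimuli)[, c("onset", "duration",
                                               "amplitude", "node_lo",
                                               "node_hi")])
  stim[, 4] <- stim[, 4] - 1
  stim[, 5] <- stim[, 5] - 1
  res <- cpp_sim_cable(config$code, cable_param_sets(config),
                       cable_node_set(config), init_state,
                       config$d_profile, config$dx, dt, duration, stim,
                       record_dt, integer(0), snapshot_times)
  structure(
    list(time = res$time, v = res$v, config = config,
         final_state = res$final_state, snapshots = res$snapshots,
         dt = dt),
    class = "cable_spacetime"
  )
}

#' @export
print.cable_spacetime <- function(x, ...) {
  cat(sprintf("<cable_spacetime> %d nodes x %d samples (%.0f ms)\n",
              ncol(x$v), nrow(x$v), max(x$time)))
  invisible(x)
}

#' Per-node activation times of a space-time record
#'
#' @param spacetime A `cable_spacetime`.
#' @param after Only crossings at `time > after` count, ms.
#' @param threshold Upstroke threshold, mV (rising crossing).
#' @return Numeric vector (ms), NA where a node never activates.
#' @export
activation_times <- function(spacetime, after = 0, threshold = -40) {
  t <- spacetime$time
  apply(spacetime$v, 2, function(v) {
    idx <- which(t > after & v >= threshold &
                   c(-Inf, v[-length(v)]) < threshold)
    if (length(idx)) t[idx[1]] else NA_real_
  })
}

#' Conduction velocity from a space-time record
#'
#' Distance over activation-time difference between two fractional positions
#' of the strand (upstroke = rising -40 mV crossing).  mm/ms equals m/s.
#'
#' @inheritParams activation_times
#' @param from_fraction,to_fraction Measurement positions as fractions of
#'   strand length.
#' @return Conduction velocity, m/s.
#' @export
measure_cv <- function(spacetime, from_fraction = 0.25, to_fraction = 0.75,
                       after = 0) {
  n <- ncol(spacetime$v)
  i0 <- max(1L, round(from_fraction * n))
  i1 <- min(n, round(to_fraction * n))
  at <- activation_times(spacetime, after = after)
  if (any(is.na(at[i0:i1])))
    stop("conduction block within the measurement segment")
  dtime <- at[i1] - at[i0]
  if (dtime <= 0) stop("non-positive activation-time difference")
  (i1 - i0) * spacetime$config$dx / dtime
}

#' Calibrate the diffusion coefficient against a target conduction velocity
#'
#' Bisection on the scalar diffusion coefficient of a homogeneous strand
#' until the measured CV is within `tolerance` of `target_cv`.  The strand
#' is tiled with the 1 Hz-preconditioned single-cell state and stimulated
#' once at one end.
#'
#' @param config A homogeneous [cable_config()] (its `d_profile` is
#'   ignored; the scalar D is the search variable).
#' @param target_cv Target conduction velocity, m/s.
#' @param tolerance Absolute CV tolerance, m/s.
#' @param bracket Initial D bracket, mm^2/ms.
#' @param precondition_beats Conditioning beats for the template cell.
#' @param dt Integration step, ms.
#' @param max_iter Bisection iteration cap.
#' @return A list: `D` (mm^2/ms), `cv` (m/s), `iterations`, and the
#'   preconditioned `init_state` used.
#' @export
calibrate_diffusion <- function(config, target_cv = 1.3, tolerance = 0.01,
                                bracket = c(0.02, 1.5),
                                precondition_beats = 100,
                                dt = default_dt(config$code),
                                max_iter = 60) {
  init <- cable_init_state(config, precondition_beats = precondition_beats,
                           dt = dt)
  stim_hi <- max(3, round(2 / config$dx))  # ~2 mm stimulated segment
  cv_of <- function(D) {
    cfg <- config
    cfg$d_profile <- rep(D, config$n_nodes)
    run <- solve_cable(cfg,
                       data.frame(onset = 5, duration = 2, amplitude = 30,
                                  node_lo = 1, node_hi = stim_hi),
                       duration = 5 + config$n_nodes * config$dx / 0.1 + 100,
                       dt = dt, record_dt = 0.25, init_state = init)
    measure_cv(run)
  }
  lo <- bracket[1]; hi <- bracket[2]
  cv_lo <- tryCatch(cv_of(lo), error = function(e) NA_real_)
  cv_hi <- cv_of(hi)
  if (!is.na(cv_lo) && cv_lo > target_cv)
    stop("bracket failure: CV at lower D already exceeds target")
  if (cv_hi < target_cv)
    stop("bracket failure: CV at upper D below target")
  it <- 0; D <- NA; cv <- NA
  repeat {
    it <- it + 1
    D <- 0.5 * (lo + hi)
    cv <- tryCatch(cv_of(D), error = function(e) NA_real_)
    if (!is.na(cv) && abs(cv - target_cv) <= tolerance) break
    if (is.na(cv) || cv < target_cv) lo <- D else hi <- D
    if (it >= max_iter)
      stop("calibration failed to reach tolerance in ", max_iter,
           " iterations")
  }
  list(D = D, cv = cv, iterations = it, init_state = init)
}

# ---- S1S2 vulnerability at the heterogeneous junction ----------------------

#' Diastolic stimulation threshold of a strand site
#'
#' Bisects the amplitude of a 2 ms pulse at the given site until the minimal
#' amplitude that elicits a propagated response from the resting strand is
#' found.  Stimulus amplitudes for S1S2 protocols are conventionally set to
#' twice this threshold.
#'
#' @param config A [cable_config()].
#' @param init_state Resting (recovered) strand state.
#' @param stim_nodes `c(lo, hi)` 1-based node range of the site.
#' @param stim_duration Pulse duration, ms.
#' @param dt Integration step, ms.
#' @param bracket Amplitude bracket, pA/pF.
#' @param rel_tol Relative bisection tolerance.
#' @return Threshold amplitude, pA/pF.
#' @export
diastolic_threshold <- function(config, init_state, stim_nodes,
                                stim_duration = 2,
                                dt = default_dt(config$code),
                                bracket = c(1, 100), rel_tol = 0.05) {
  probe <- unique(pmax(1, pmin(config$n_nodes,
                               c(stim_nodes[1] - 10, stim_nodes[2] + 10))))
  captures <- function(amp) {
    run <- solve_cable(config,
                       data.frame(onset = 2, duration = stim_duration,
                                  amplitude = amp, node_lo = stim_nodes[1],
                                  node_hi = stim_nodes[2]),
                       duration = 80, dt = dt, record_dt = 0.5,
                       init_state = init_state)
    any(!is.na(activation_times(run, after = 2)[probe]))
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (captures(lo)) return(lo)
  if (!captures(hi)) stop("no capture at the upper amplitude bracket")
  while ((hi - lo) / hi > rel_tol) {
    mid <- 0.5 * (lo + hi)
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Condition a strand with an S1 train at the CT/PM junction
#'
#' Runs `n_s1 - 1` junction stimuli and returns the cached full state at the
#' onset time of the final S1, so that S2 trials at many coupling intervals
#' can resume from it (the final S1 and the S2 are delivered in the trial
#' run itself).
#'
#' @param config A [cable_config()].
#' @param n_s1 Number of S1 stimuli.
#' @param s1_cl S1 cycle length, ms.
#' @param stim_nodes 1-based node range of the stimulus site; defaults to a
#'   3.3 mm-radius segment centred on the strand midpoint (the junction).
#' @param stim_amplitude,stim_duration Stimulus shape; `NULL` amplitude
#'   means twice the measured diastolic threshold at the site (see
#'   [diastolic_threshold()]).
#' @param dt Integration step, ms.
#' @param precondition_beats Single-cell conditioning of the region
#'   templates before the train.
#' @param acute_iso `FALSE` (default): the strand is conditioned with its
#'   own (possibly ISO-carrying) parameter set, i.e. ISO is present
#'   throughout the protocol, matching a uniform-ISO S1S2 configuration.
#'   `TRUE`: condition without ISO and switch the ISO set on with the first
#'   protocol stimulus (acute wash-in).
#' @return A list used by [s1s2_outcome()] / [vulnerability_window()].
#' @export
s1s2_prepare <- function(config, n_s1 = 7, s1_cl = 500, stim_nodes = NULL,
                         stim_amplitude = NULL, stim_duration = 2,
                         dt = default_dt(config$code),
                         precondition_beats = 50, acute_iso = FALSE) {
  if (is.null(stim_nodes)) {
    # the junction stimulus covers a 3.3 mm-radius segment
    mid <- config$n_nodes / 2
    r <- round(3.3 / config$dx)
    stim_nodes <- c(max(1, floor(mid - r)),
                    min(config$n_nodes, ceiling(mid + r)))
  }
  # the diastolic threshold is determined on the baseline (ISO-free)
  # resting strand, as in experimental practice
  if (is.null(stim_amplitude)) {
    base_cfg <- config
    base_cfg$cells <- lapply(config$cells, function(c)
      build_cell(c$model_id, c$region, c$mutation, c$caf, iso = FALSE))
    base_init <- cable_init_state(base_cfg,
                                  precondition_beats = precondition_beats,
                                  cl = 1000, dt = dt)
    settle <- solve_cable(base_cfg,
                          data.frame(onset = 0, duration = 0, amplitude = 0,
                                     node_lo = 1, node_hi = 1),
                          duration = 1000, dt = dt, record_dt = 1000,
                          init_state = base_init)
    thr <- diastolic_threshold(base_cfg, settle$final_state, stim_nodes,
                               stim_duration = stim_duration, dt = dt)
    stim_amplitude <- 2 * thr
  }
  init <- cable_init_state(config,
                           precondition_beats = precondition_beats,
                           cl = 1000, dt = dt, acute_iso = acute_iso)
  onsets <- 10 + (seq_len(n_s1 - 1) - 1) * s1_cl
  run <- solve_cable(config,
                     data.frame(onset = onsets, duration = stim_duration,
                                amplitude = stim_amplitude,
                                node_lo = stim_nodes[1],
                                node_hi = stim_nodes[2]),
                     duration = 10 + (n_s1 - 1) * s1_cl, dt = dt,
                     record_dt = 1, init_state = init)
  list(config = config, state = run$final_state, stim_nodes = stim_nodes,
       stim_amplitude = stim_amplitude, stim_duration = stim_duration,
       dt = dt)
}

#' Classify the outcome of one S2 coupling interval
#'
#' Resumes from the cached post-S1 state, delivers the final S1 and the S2
#' at the junction, and classifies whether the S2 wave reaches each strand
#' end: `bidirectional_conduction`, `bidirectional_block`,
#' `unidirectional_block_A` (blocked toward the A/left/CT end) or
#' `unidirectional_block_B` (blocked toward the B/right/PM end).
#'
#' @param prep Result of [s1s2_prepare()].
#' @param s2 S2 coupling interval, ms (from the final S1).
#' @param travel_ms Detection window after the S2 stimulus, ms.
#' @return A one-row tibble: `s2`, `outcome`, `reached_a`, `reached_b`.
#' @export
s1s2_outcome <- function(prep, s2, travel_ms = 400) {
  cfg <- prep$config
  run <- solve_cable(cfg,
                     data.frame(onset = c(0, s2),
                                duration = prep$stim_duration,
                                amplitude = prep$stim_amplitude,
                                node_lo = prep$stim_nodes[1],
                                node_hi = prep$stim_nodes[2]),
                     duration = s2 + travel_ms, dt = prep$dt,
                     record_dt = 1, init_state = prep$state)
  at <- activation_times(run, after = s2)
  sensor_a <- 3L
  sensor_b <- cfg$n_nodes - 2L
  reached_a <- !is.na(at[sensor_a]) && at[sensor_a] <= s2 + travel_ms
  reached_b <- !is.na(at[sensor_b]) && at[sensor_b] <= s2 + travel_ms
  outcome <- if (reached_a && reached_b) "bidirectional_conduction"
             else if (!reached_a && !reached_b) "bidirectional_block"
             else if (!reached_a) "unidirectional_block_A"
             else "unidirectional_block_B"
  tibble::tibble(s2 = s2, outcome = outcome, reached_a = reached_a,
                 reached_b = reached_b)
}

#' Temporal vulnerability window to unidirectional conduction block
#'
#' Coarse scan of S2 coupling intervals followed by bisection of both
#' boundaries to the requested resolution.  The vulnerability window is the
#' temporal range of S2 whose outcome is unidirectional block (wave break in
#' one direction but not both).  A strand with no unidirectional outcomes
#' has width 0.
#'
#' @inheritParams s1s2_outcome
#' @param scan `c(lo, hi)` S2 range to search, ms.
#' @param resolution Boundary resolution, ms.
#' @param coarse Coarse scan step, ms.
#' @return A one-row tibble of class `vulnerability_window`: `s2_low`,
#'   `s2_high`, `width`, `resolution`, with the scan table in attribute
#'   `outcomes`.
#' @export
vulnerability_window <- function(prep, scan = c(150, 800), resolution = 1,
                                 coarse = 10) {
  s2s <- seq(scan[1], scan[2], by = coarse)
  out <- dplyr::bind_rows(lapply(s2s, function(s) s1s2_outcome(prep, s)))
  uni <- grepl("^unidirectional", out$outcome)
  if (!any(uni)) {
    res <- tibble::tibble(s2_low = NA_real_, s2_high = NA_real_, width = 0,
                          resolution = resolution)
    attr(res, "outcomes") <- out
    class(res) <- c("vulnerability_window", class(res))
    return(res)
  }
  if (any(diff(which(uni)) > 1))
    warning("non-contiguous unidirectional range in coarse scan")
  is_uni <- function(s2) grepl("^unidirectional",
                               s1s2_outcome(prep, s2)$outcome)
  # refine a boundary between a uni point and a non-uni point
  refine <- function(s_uni, s_non) {
    while (abs(s_non - s_uni) > resolution) {
      mid <- round((s_uni + s_non) / 2 / resolution) * resolution
      if (mid == s_uni || mid == s_non) break
      if (is_uni(mid)) s_uni <- mid else s_non <- mid
    }
    s_uni
  }
  first_uni <- s2s[which(uni)[1]]
  last_uni <- s2s[which(uni)[length(which(uni))]]
  s2_low <- if (which(uni)[1] == 1) first_uni
            else refine(first_uni, s2s[which(uni)[1] - 1])
  s2_high <- if (which(uni)[length(which(uni))] == length(s2s)) last_uni
             else refine(last_uni, s2s[which(uni)[length(which(uni))] + 1])
  res <- tibble::tibble(s2_low = s2_low, s2_high = s2_high,
                        width = s2_high - s2_low, resolution = resolution)
  attr(res, "outcomes") <- out
  class(res) <- c("vulnerability_window", class(res))
  res
}

# ---- sinus-driven conduction patterns --------------------------------------

#' Conduction pattern of sinus beats through CT/PM pathways
#'
#' A 1D strand laid out as PM | CT | SAN-surrogate | CT | PM.  The sinoatrial
#' node is represented by a periodic suprathreshold stimulus train applied to
#' the central segment (a pacing surrogate for a detailed SAN cell model).
#' Each sinus beat is labelled conducted or blocked in each direction by
#' whether its wavefront reaches the strand ends.
#'
#' @param model_id,mutation,caf Cell options (see [build_cell()]).
#' @param iso `"none"`, `"uniform"`, `"left"`, or `"right"`: which flank
#'   segments receive the isoprenaline parameter set.
#' @param n_beats Number of sinus beats.
#' @param cl Sinus cycle length, ms.
#' @param seg_nodes Nodes per segment: `c(pm, ct, san, ct, pm)`.
#' @param dx,D,dt Discretisation and coupling.
#' @param stim_amplitude,stim_duration SAN-surrogate stimulus shape.
#' @param precondition_beats Single-cell conditioning of region templates.
#' @return A tibble (`beat`, `left_conducted`, `right_conducted`) of class
#'   `san_pattern`, with the space-time record in attribute `spacetime`.
#' @export
san_conduction_pattern <- function(model_id = "grandi", mutation = "WT",
                                   caf = FALSE,
                                   iso = c("none", "uniform", "left",
                                           "right"),
                                   n_beats = 6, cl = 750,
                                   seg_nodes = c(55, 30, 12, 30, 55),
                                   dx = 0.25, D = 0.1,
                                   dt = NULL, stim_amplitude = 25,
                                   stim_duration = 2,
                                   precondition_beats = 50) {
  iso <- match.arg(iso)
  iso_left <- iso %in% c("uniform", "left")
  iso_right <- iso %in% c("uniform", "right")
  cells <- list(
    PM_L = build_cell(model_id, "PM", mutation, caf, iso_left),
    CT_L = build_cell(model_id, "CT", mutation, caf, iso_left),
    SAN = build_cell(model_id, "RA", mutation, caf, FALSE),
    CT_R = build_cell(model_id, "CT", mutation, caf, iso_right),
    PM_R = build_cell(model_id, "PM", mutation, caf, iso_right)
  )
  labels <- rep(names(cells), times = seg_nodes)
  cfg <- cable_config(cells, n_nodes = sum(seg_nodes), dx = dx, D = D,
                      region_labels = labels)
  if (is.null(dt)) dt <- default_dt(cfg$code)
  san_lo <- sum(seg_nodes[1:2]) + 1
  san_hi <- sum(seg_nodes[1:3])
  onsets <- 10 + (seq_len(n_beats) - 1) * cl
  base_cfg <- cfg
  base_cfg$cells <- lapply(cfg$cells, function(c)
    build_cell(c$model_id, c$region, c$mutation, c$caf, iso = FALSE))
  init <- cable_init_state(base_cfg, precondition_beats = precondition_beats,
                           cl = 1000, dt = dt)
  relax <- solve_cable(base_cfg,
                       data.frame(onset = 0, duration = 0, amplitude = 0,
                                  node_lo = 1, node_hi = 1),
                       duration = 1000, dt = dt, record_dt = 1000,
                       init_state = init)
  init <- relax$final_state
  run <- solve_cable(cfg,
                     data.frame(onset = onsets, duration = stim_duration,
                                amplitude = stim_amplitude,
                                node_lo = san_lo, node_hi = san_hi),
                     duration = max(onsets) + cl, dt = dt, record_dt = 1,
                     init_state = init)
  t <- run$time
  crossings <- function(node) {
    v <- run$v[, node]
    t[v >= -40 & c(-Inf, v[-length(v)]) < -40]
  }
  left_x <- crossings(3L)
  right_x <- crossings(cfg$n_nodes - 2L)
  rows <- lapply(seq_len(n_beats), function(b) {
    w0 <- onsets[b]; w1 <- onsets[b] + cl
    tibble::tibble(beat = b,
                   left_conducted = any(left_x >= w0 & left_x < w1),
                   right_conducted = any(right_x >= w0 & right_x < w1))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "spacetime") <- run
  class(out) <- c("san_pattern", class(out))
  out
}
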