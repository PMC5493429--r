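#' Phase library: state snapshots across one action-potential cycle
#'
#' Paces a cell to steady state at the given cycle length, then records full
#' state snapshots at uniform intervals across the final cycle.  Distributing
#' these snapshots across a sheet (phase-distribution initiation) starts a
#' re-entrant wave without any stimulus sequence.
#'
#' @param cell A [build_cell()] object.
#' @param cycle_length Pacing cycle length, ms.
#' @param n_snapshots Number of snapshots (>= 32 recommended; < 2 is
#'   degenerate and rejected).
#' @param n_beats Conditioning beats before the recorded cycle.
#' @param dt Integration step, ms.
#' @return An object of class `phase_library`: list of state vectors plus
#'   the cycle length.
#' @export
build_phase_library <- function(cell, cycle_length = 1000, n_snapshots = 64,
                                n_beats = 50, dt = default_dt(cell$code)) {
  if (n_snapshots < 2) stop("degenerate phase library: need >= 2 snapshots")
  onset0 <- 10
  stim_times <- onset0 + (seq_len(n_beats) - 1) * cycle_length
  last <- stim_times[n_beats]
  snap_times <- last + (seq_len(n_snapshots) - 1) / n_snapshots * cycle_length
  stim <- cbind(stim_times, 2, 25, 0, 0)
  res <- cpp_sim_cable(cell$code, list(cell$params), 0L,
                       matrix(cell$state, ncol = 1), 0, 0.25, dt,
                       last + cycle_length, stim, 1, 0L, snap_times)
  states <- lapply(res$snapshots, function(s) s[, 1])
  structure(
    list(states = states, cycle_length = cycle_length,
         n_snapshots = n_snapshots, cell = cell),
    class = "phase_library"
  )
}

#' @export
print.phase_library <- function(x, ...) {
  vs <- vapply(x$states, function(s) s[1], numeric(1))
  cat(sprintf("<phase_library> %d snapshots over %.0f ms (V %.1f..%.1f mV)\n",
              x$n_snapshots, x$cycle_length, min(vs), max(vs)))
  invisible(x)
}

#' 2D sheet configuration
#'
#' A homogeneous monodomain sheet with uniform diffusion `d_scale * D_base`.
#' The diffusion scale models gap-junction/structural remodelling: 1 is
#' control (lone AF), smaller values down to 0.4 represent severe
#' remodelling.
#'
#' @param cell A [build_cell()] object used at every node.
#' @param nx,ny Grid size (nodes).
#' @param dx Node spacing, mm.
#' @param D_base Control diffusion coefficient, mm^2/ms.
#' @param d_scale Fraction of control diffusion, in (0, 1].
#' @return An object of class `sheet_config`.
#' @export
sheet_config <- function(cell, nx = 160, ny = 160, dx = 0.25,
                         D_base = 0.1, d_scale = 1) {
  stopifnot(inherits(cell, "cell_instance"), nx * ny <= 1e6,
            d_scale > 0, d_scale <= 1)
  structure(list(cell = cell, nx = nx, ny = ny, dx = dx, D_base = D_base,
                 d_scale = d_scale, D = D_base * d_scale),
            class = "sheet_config")
}

#' Initial state field from a phase library
#'
#' Assigns each sheet node the library snapshot indexed by its layout phase:
#' `"linear"` (phase proportional to x; a planar phase gradient),
#' `"archimedean"` (phase proportional to the angle about `phase_center`
#' plus a radial term; seeds a single rotor), or `"uniform"` (all nodes at
#' phase 0; control, no wave develops).
#'
#' @param sheet A [sheet_config()].
#' @param library A [build_phase_library()] result.
#' @param layout `"archimedean"`, `"linear"` or `"uniform"`.
#' @param phase_center `c(x, y)` node coordinates of the rotor core
#'   (defaults to the sheet centre).
#' @param mirror Flip chirality (mirrors the layout in y).
#' @return A state matrix (n_state x nx*ny) for [run_reentry()].
#' @export
init_sheet_phase_map <- function(sheet, library,
                                 layout = c("archimedean", "linear",
                                            "uniform"),
                                 phase_center = NULL, mirror = FALSE) {
  layout <- match.arg(layout)
  stopifnot(inherits(library, "phase_library"))
  nx <- sheet$nx; ny <- sheet$ny
  if (is.null(phase_center)) phase_center <- c(nx / 2, ny / 2)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  if (mirror) iy <- ny + 1 - iy
  phase <- switch(layout,
    uniform = rep(0, nx * ny),
    linear = (ix - 1) / nx,
    archimedean = {
      ang <- atan2(iy - phase_center[2], ix - phase_center[1])
      r <- sqrt((ix - phase_center[1])^2 + (iy - phase_center[2])^2)
      rmax <- max(r)
      (ang / (2 * pi) + 0.5 * r / rmax) %% 1
    }
  )
  idx <- pmin(library$n_snapshots,
              floor(phase * library$n_snapshots) + 1L)
  mat <- vapply(library$states, identity,
                numeric(length(library$states[[1]])))
  mat[, idx, drop = FALSE]
}

#' Run a 2D re-entry simulation and summarise its dynamics
#'
#' Simulates the sheet from a phase-mapped (or other) initial state,
#' recording membrane voltage at a grid of distributed sites and the
#' field-wide maximum voltage.  Re-entry is `sustained` if any site still
#' activates in the final 250 ms; `lifetime` is the last activation time
#' anywhere in the field; per-site dominant frequencies are computed by
#' Fourier analysis over the analysis window.
#'
#' @param sheet A [sheet_config()].
#' @param init_state State matrix from [init_sheet_phase_map()], or `NULL`
#'   for the resting sheet.
#' @param duration Simulated (and analysed) time, ms.
#' @param stimuli Optional data frame of rectangle stimuli: columns `onset`,
#'   `duration`, `amplitude`, `x0`, `x1`, `y0`, `y1` (1-based node coords).
#' @param n_sites Sites per side of the recording grid (n_sites^2 total,
#'   >= 3 recommended).
#' @param record_dt Site-trace sampling interval, ms.
#' @param dt Integration step, ms.
#' @param df_window Dominant-frequency analysis window (taken from the end
#'   of the record), ms.
#' @param field_times Times at which to keep voltage-field snapshots, ms.
#' @return An object of class `reentry_metrics`: tibble of per-site dominant
#'   frequencies with attributes `sustained`, `lifetime`, `site_traces`,
#'   `vmax`, `fields`.
#' @export
run_reentry <- function(sheet, init_state = NULL, duration = 5000,
                        stimuli = NULL, n_sites = 3, record_dt = 1,
                        dt = default_dt(sheet$cell$code), df_window = 2000,
                        field_times = numeric(0)) {
  stopifnot(inherits(sheet, "sheet_config"))
  if (sheet$D > 0 && dt > sheet$dx^2 / (4 * sheet$D))
    stop("dt violates the 2D diffusion stability bound dx^2/(4 D)")
  nx <- sheet$nx; ny <- sheet$ny
  sx <- round(seq(0.2, 0.8, length.out = n_sites) * nx)
  sy <- round(seq(0.2, 0.8, length.out = n_sites) * ny)
  sites <- as.integer(outer(sx, (sy - 1) * nx, `+`)) - 1L
  stim <- if (is.null(stimuli)) {
    matrix(numeric(0), ncol = 7)
  } else {
    m <- as.matrix(as.data.frame(stimuli)[, c("onset", "duration",
                                              "amplitude", "x0", "x1",
                                              "y0", "y1")])
    m[, 4:7] <- m[, 4:7] - 1
    m
  }
  res <- cpp_sim_sheet(sheet$cell$code, sheet$cell$params, nx, ny,
                       init_state, sheet$D, sheet$dx, dt, duration, stim,
                       sites, record_dt, field_times)
  t <- res$time
  act_any <- res$vmax >= -40
  lifetime <- if (any(act_any)) max(t[act_any]) else 0
  site_act <- apply(res$site_v, 2, function(v)
    any(t >= duration - 250 & v >= -40 & c(-Inf, v[-length(v)]) < -40))
  sustained <- lifetime >= duration - record_dt ||
    (any(site_act) && lifetime >= duration - 250)
  dfs <- apply(res$site_v, 2, function(v)
    dominant_frequency(v, t, window = min(df_window, duration)))
  out <- tibble::tibble(site = seq_along(dfs), df_hz = dfs)
  attr(out, "sustained") <- sustained
  attr(out, "lifetime") <- lifetime
  attr(out, "site_traces") <- res$site_v
  attr(out, "time") <- t
  attr(out, "vmax") <- res$vmax
  attr(out, "fields") <- res$fields
  attr(out, "duration") <- duration
  class(out) <- c("reentry_metrics", class(out))
  out
}

#' @export
print.reentry_metrics <- function(x, ...) {
  cat(sprintf(
    "<reentry_metrics> sustained: %s, lifetime %.0f ms, median DF %.2f Hz\n",
    attr(x, "sustained"), attr(x, "lifetime"),
    stats::median(x$df_hz, na.rm = TRUE)))
  invisible(x)
}

#' Dominant frequency of a voltage trace
#'
#' Mean-removed, Hann-tapered periodogram over the analysis window; the
#' dominant frequency is the frequency of maximal spectral power above
#' 0.5 Hz (excluding DC/drift).  Spectral resolution is 1/window.  A
#' quiescent trace (peak-to-peak < 1 mV) reports 0 Hz.
#'
#' @param v Voltage samples, mV.
#' @param t Sample times, ms (uniform).
#' @param window Analysis window taken from the end of the trace, ms
#'   (>= 2000 recommended).
#' @return Dominant frequency, Hz.
#' @export
dominant_frequency <- function(v, t, window = max(t) - min(t)) {
  sel <- t >= max(t) - window
  v <- v[sel]
  n <- length(v)
  if (n < 8 || diff(range(v)) < 1) return(0)
  dt_s <- (t[2] - t[1]) / 1000
  x <- v - mean(v)
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  sp <- Mod(stats::fft(x * hann))^2
  freq <- (seq_len(n) - 1) / (n * dt_s)
  keep <- freq >= 0.5 & freq <= 1 / (2 * dt_s)
  if (!any(keep)) return(0)
  freq[keep][which.max(sp[keep])]
}
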