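model_code <- function(model_id) {
  switch(model_id, courtemanche = 0L, courtemanche_newIKur = 0L,
         grandi = 1L,
         stop("unknown model_id: ", model_id))
}

#' Regional electrophysiology scalings (provisional)
#'
#' Conductance scalings for the right-atrial bundle regions relative to the
#' baseline right-atrial (RA) cell: the crista terminalis (CT) carries a
#' larger L-type Ca current (prominent plateau, longer APD), the pectinate
#' muscles (PM) a slightly smaller one with a larger transient outward
#' current.  Values follow the regional-model lineage the atrial literature
#' uses for these bundles; exact published supplements differ, so these are
#' editable, provisional defaults.
#'
#' @return A tibble with columns `region`, `gcal_f`, `gto_f`.
#' @export
regional_scalings <- function() {
  tibble::tribble(
    ~region, ~gcal_f, ~gto_f,
    "RA", 1.00, 1.00,
    "CT", 1.32, 0.80,
    "PM", 0.90, 1.20
  )
}

#' Chronic-AF electrical remodelling scalings (Courtemanche lineage)
#'
#' The Grandi-lineage model carries its own native chronic-AF parameter set;
#' for the Courtemanche lineage the standard remodelling set is applied:
#' ICaL and Ito reduced to 35%, IKur halved, IK1 doubled.
#'
#' @return Named list of conductance factors.
#' @export
caf_scalings <- function() {
  list(gcal_f = 0.35, gto_f = 0.35, gkur_f = 0.5, gk1_f = 2.0)
}

# Courtemanche-lineage parameter vector (see src/models.h layout)
ctm_params <- function(region, mutation, caf, iso, new_ikur) {
  reg <- regional_scalings()
  reg <- reg[reg$region == region, ]
  if (nrow(reg) != 1) stop("unknown region: ", region)
  delta <- variant_delta(mutation)
  g <- list(gna = 1, gto = reg$gto_f, gcal = reg$gcal_f, gkr = 1, gks = 1,
            gk1 = 1, gkur = 1, gnak = 1, gncx = 1, gup = 1, kup = 1)
  if (caf) {
    cf <- caf_scalings()
    g$gcal <- g$gcal * cf$gcal_f; g$gto <- g$gto * cf$gto_f
    g$gkur <- g$gkur * cf$gkur_f; g$gk1 <- g$gk1 * cf$gk1_f
  }
  d_shift <- 0; xs_shift <- 0
  if (iso) {
    # beta-adrenergic stimulation transferred as the same fractional changes
    # applied to the homologous currents of the Grandi-lineage set
    g$gcal <- g$gcal * 1.5; g$gks <- g$gks * 3; g$gkur <- g$gkur * 3
    g$kup <- 0.5; d_shift <- -3; xs_shift <- -40
  }
  if (!new_ikur) {
    # native I_Kur gating; variant shifts applied to the native Boltzmanns
    ma <- min(max(0 + delta$d_ma, 0), 1 - 1e-9)
    c(g$gna, g$gto, g$gcal, g$gkr, g$gks, g$gk1, g$gkur * delta$g_factor,
      g$gnak, g$gncx, g$gup, g$kup,
      0,                                      # ikur_mode native
      1, -30.3 + delta$d_vhalf_act, -9.6 * delta$k_act_factor, 0, 1,
      99.45 + delta$d_vhalf_inact, 27.48 * delta$k_inact_factor,
      1 - ma, ma, d_shift, xs_shift)
  } else {
    mdl <- if (identical(canonical_mutation(mutation), "WT")) ikur_model()
           else apply_mutant(mutation)
    act <- mdl$act_ss
    a2 <- if (length(act) == 2) act[[2]] else boltzmann_params(0, 1)
    c(g$gna, g$gto, g$gcal, g$gkr, g$gks, g$gk1, g$gkur * mdl$g_factor,
      g$gnak, g$gncx, g$gup, g$kup,
      1,                                      # new formulation
      length(act), act[[1]]$v_half, act[[1]]$slope_k, a2$v_half, a2$slope_k,
      mdl$inact_ss$v_half, mdl$inact_ss$slope_k, mdl$inact_ss$amplitude,
      mdl$inact_ss$floor_ma, d_shift, xs_shift)
  }
}

# Grandi-lineage parameter vector
grandi_params <- function(region, mutation, caf, iso) {
  reg <- regional_scalings()
  reg <- reg[reg$region == region, ]
  if (nrow(reg) != 1) stop("unknown region: ", region)
  delta <- variant_delta(mutation)
  ma <- min(max(0 + delta$d_ma, 0), 1 - 1e-9)
  c(as.numeric(caf), as.numeric(iso),
    1, reg$gto_f, reg$gcal_f, 1, 1, 1, delta$g_factor, 1, 1, 1,
    -6 + delta$d_vhalf_act, -8.6 * delta$k_act_factor,
    -7.5 + delta$d_vhalf_inact, 10 * delta$k_inact_factor, ma)
}

#' Build a human atrial cell instance
#'
#' Constructs a single-cell model: `"courtemanche"` (native I_Kur gating),
#' `"courtemanche_newIKur"` (the Courtemanche-lineage model with the new
#' voltage-dependent-conductance I_Kur formulation swapped in), or
#' `"grandi"` (compartmental model with native chronic-AF and
#' beta-adrenergic parameter sets).  Variant I_Kur parameter changes, the
#' regional (RA/CT/PM) scalings, chronic-AF remodelling and the 1 uM
#' isoprenaline (ISO) set are applied multiplicatively/additively on top.
#'
#' @param model_id One of `"courtemanche"`, `"courtemanche_newIKur"`,
#'   `"grandi"`.
#' @param region `"RA"`, `"CT"` or `"PM"`.
#' @param mutation `"WT"` or one of the six KCNA5 variants (see
#'   [kcna5_variants()]).
#' @param caf Apply chronic-AF electrical remodelling?
#' @param iso Apply the 1 uM isoprenaline (beta-adrenergic) parameter set?
#' @return An object of class `cell_instance`.
#' @examples
#' cell <- build_cell("courtemanche")
#' cell
#' @export
build_cell <- function(model_id = c("courtemanche", "courtemanche_newIKur",
                                    "grandi"),
                       region = c("RA", "CT", "PM"), mutation = "WT",
                       caf = FALSE, iso = FALSE) {
  model_id <- match.arg(model_id)
  region <- match.arg(region)
  mutation <- canonical_mutation(mutation)
  code <- model_code(model_id)
  params <- if (code == 0L) {
    ctm_params(region, mutation, caf, iso, model_id == "courtemanche_newIKur")
  } else {
    grandi_params(region, mutation, caf, iso)
  }
  structure(
    list(model_id = model_id, region = region, mutation = mutation,
         caf = caf, iso = iso, code = code, params = params,
         state = cpp_model_default_state(code)),
    class = "cell_instance"
  )
}

#' @export
print.cell_instance <- function(x, ...) {
  cat(sprintf("<cell_instance> %s %s %s%s%s (%d states)\n", x$model_id,
              x$region, x$mutation, if (x$caf) " +cAF" else "",
              if (x$iso) " +ISO" else "", length(x$state)))
  invisible(x)
}

#' Replace the state of a cell instance
#'
#' Used to hand a preconditioned state to a differently parameterised cell
#' (e.g. acute isoprenaline wash-in after drug-free pacing).
#'
#' @param cell A [build_cell()] object.
#' @param state Numeric state vector of the model's dimension.
#' @export
set_cell_state <- function(cell, state) {
  stopifnot(inherits(cell, "cell_instance"),
            length(state) == length(cell$state))
  cell$state <- as.numeric(state)
  cell
}

#' Pacing protocol
#'
#' A conditioning train of `n_s1` stimuli at cycle length `s1_cl`, optionally
#' followed by a premature stimulus `s2` ms after the final S1.
#'
#' @param n_s1 Number of S1 stimuli.
#' @param s1_cl S1 cycle length, ms.
#' @param s2 Optional S1-S2 coupling interval, ms.
#' @param stim_amplitude Stimulus amplitude, pA/pF (depolarising positive).
#' @param stim_duration Stimulus duration, ms.
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(n_s1 = 10, s1_cl = 1000, s2 = NULL,
                            stim_amplitude = 25, stim_duration = 2) {
  stopifnot(n_s1 >= 1, s1_cl > stim_duration, is.null(s2) || s2 > 0)
  structure(list(n_s1 = n_s1, s1_cl = s1_cl, s2 = s2,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration),
            class = "pacing_protocol")
}

default_dt <- function(code) if (code == 0L) 0.01 else 0.005

#' Pace a single cell and record its membrane voltage
#'
#' Fixed-step integration (Rush-Larsen exponential updates for
#' voltage-dependent gates over tabulated rates, forward Euler elsewhere).
#' Deterministic: identical inputs give bit-identical traces.
#'
#' @param cell A [build_cell()] object (its `state` field is the initial
#'   condition).
#' @param protocol A [pacing_protocol()].
#' @param dt Integration step, ms.
#' @param record_dt Sampling interval of the returned trace, ms.
#' @param tail_ms Extra quiescent time simulated after the final stimulus
#'   interval, ms.
#' @return A tibble (`time_ms`, `v_mV`) with attributes `stim_times`,
#'   `final_state`, `protocol`.
#' @examples
#' tr <- pace(build_cell("courtemanche"), pacing_protocol(n_s1 = 2))
#' measure_ap(tr, beat = 2)
#' @export
pace <- function(cell, protocol = pacing_protocol(),
                 dt = default_dt(cell$code), record_dt = 0.5, tail_ms = 0) {
  stopifnot(inherits(cell, "cell_instance"),
            inherits(protocol, "pacing_protocol"))
  onset0 <- 10
  stim_times <- onset0 + (seq_len(protocol$n_s1) - 1) * protocol$s1_cl
  if (!is.null(protocol$s2))
    stim_times <- c(stim_times, stim_times[length(stim_times)] + protocol$s2)
  stim <- cbind(stim_times, protocol$stim_duration, protocol$stim_amplitude,
                0, 0)
  duration <- max(stim_times) + protocol$s1_cl + tail_ms
  res <- cpp_sim_cable(cell$code, list(cell$params), 0L,
                       matrix(cell$state, ncol = 1), 0, 0.25, dt, duration,
                       stim, record_dt, 0L, numeric(0))
  out <- tibble::tibble(time_ms = res$time, v_mV = res$v[, 1])
  attr(out, "stim_times") <- stim_times
  attr(out, "final_state") <- res$final_state[, 1]
  attr(out, "protocol") <- protocol
  out
}

#' Pace a cell to steady state and return the updated cell
#'
#' @inheritParams pace
#' @param n_beats Number of conditioning beats.
#' @param cl Cycle length, ms.
#' @export
precondition <- function(cell, n_beats = 100, cl = 1000,
                         dt = default_dt(cell$code)) {
  tr <- pace(cell, pacing_protocol(n_s1 = n_beats, s1_cl = cl),
             dt = dt, record_dt = 5)
  set_cell_state(cell, attr(tr, "final_state"))
}

beat_window <- function(trace, beat) {
  st <- attr(trace, "stim_times")
  if (is.null(st)) stop("trace has no stimulus-time attribute")
  if (beat < 1 || beat > length(st)) stop("beat index out of range")
  t0 <- st[beat]
  t1 <- if (beat < length(st)) st[beat + 1] else max(trace$time_ms)
  list(t0 = t0, t1 = t1)
}

#' Measure action-potential metrics of one beat
#'
#' The upstroke is the first rising crossing of -40 mV after the beat's
#' stimulus; APD_x is the time from upstroke to x% repolarisation between
#' the AP peak and the pre-stimulus diastolic voltage.  `plateau_v` is the
#' voltage midway through the APD90 interval.
#'
#' @param trace A voltage trace from [pace()].
#' @param beat Beat index (1-based within the stimulus train).
#' @return A one-row tibble: `rmp`, `peak_v`, `max_dvdt`, `apd30`, `apd90`,
#'   `plateau_v`, `ead_count`.
#' @export
measure_ap <- function(trace, beat = length(attr(trace, "stim_times"))) {
  w <- beat_window(trace, beat)
  sel <- trace$time_ms >= w$t0 - 5 & trace$time_ms < w$t1
  t <- trace$time_ms[sel]; v <- trace$v_mV[sel]
  pre <- which(t < w$t0)
  rmp <- if (length(pre)) v[pre[length(pre)]] else v[1]
  idx0 <- which(t >= w$t0)
  # upstroke = rising -40 mV crossing (a plateau already above -40 when the
  # stimulus lands is not an upstroke)
  rising <- idx0[v[idx0] > -40 & v[pmax(idx0 - 1, 1)] <= -40]
  cross <- rising[1]
  if (is.na(cross)) stop("no upstroke found in beat ", beat)
  t_up <- t[cross]
  pk <- idx0[which.max(v[idx0])]
  peak_v <- v[pk]
  max_dvdt <- max(diff(v) / diff(t))
  apd <- function(x) {
    vth <- peak_v - x / 100 * (peak_v - rmp)
    idx <- which(t > t[pk] & v <= vth)[1]
    if (is.na(idx)) return(NA_real_)
    t[idx] - t_up
  }
  apd30 <- apd(30); apd90 <- apd(90)
  plateau_v <- if (is.na(apd90)) NA_real_ else {
    v[which.min(abs(t - (t_up + apd90 / 2)))]
  }
  tibble::tibble(rmp = rmp, peak_v = peak_v, max_dvdt = max_dvdt,
                 apd30 = apd30, apd90 = apd90, plateau_v = plateau_v,
                 ead_count = detect_eads(trace, beat))
}

#' Count early-after-depolarisations (EADs) in one beat
#'
#' An EAD is a local voltage minimum followed by a local maximum rising by
#' at least `prominence` mV, both between the AP peak and the terminal
#' downward -40 mV crossing.  The first such pair after the peak is the
#' physiological phase-1 notch/dome of the AP and is excluded (set
#' `skip_dome = FALSE` to count it too).
#'
#' @inheritParams measure_ap
#' @param prominence Minimum rise from local minimum to following local
#'   maximum, mV.
#' @param skip_dome Exclude the first post-peak minimum/maximum pair?
#' @return Integer count of EADs.
#' @export
detect_eads <- function(trace, beat = length(attr(trace, "stim_times")),
                        prominence = 2, skip_dome = TRUE) {
  w <- beat_window(trace, beat)
  sel <- trace$time_ms >= w$t0 & trace$time_ms < w$t1
  t <- trace$time_ms[sel]; v <- trace$v_mV[sel]
  pk <- which.max(v)
  end <- which(t > t[pk] & v < -40)[1]
  if (is.na(end)) end <- length(v)
  n <- 0L; i <- pk + 1L; first <- TRUE
  while (i < end) {
    if (v[i] <= v[i - 1] && v[i] <= v[i + 1]) {
      j <- i
      while (j < end && v[j + 1] >= v[j]) j <- j + 1L
      if (v[j] - v[i] >= prominence) {
        if (!(first && skip_dome)) n <- n + 1L
        first <- FALSE
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  n
}

#' APD restitution by S1-S2 stimulation
#'
#' Applies an S1 conditioning train once, caches the post-train state, and
#' for each S2 coupling interval delivers a single premature stimulus and
#' measures the APD90 of the S2 beat.  S2 values that fail to capture are
#' flagged, not dropped.
#'
#' @param cell A [build_cell()] object.
#' @param s2_grid S2 coupling intervals, ms.
#' @param n_s1,s1_cl Conditioning train (count, cycle length in ms).
#' @param dt Integration step, ms.
#' @param stim_amplitude,stim_duration Stimulus shape.
#' @return A tibble (`s2`, `apd90`, `captured`) of class `restitution_curve`.
#' @export
restitution <- function(cell, s2_grid, n_s1 = 100, s1_cl = 1000,
                        dt = default_dt(cell$code), stim_amplitude = 25,
                        stim_duration = 2) {
  s2_grid <- sort(s2_grid)
  cond <- precondition(cell, n_beats = n_s1, cl = s1_cl, dt = dt)
  rows <- lapply(s2_grid, function(s2) {
    tr <- pace(cond, pacing_protocol(n_s1 = 1, s1_cl = s1_cl, s2 = s2,
                                     stim_amplitude = stim_amplitude,
                                     stim_duration = stim_duration),
               dt = dt)
    m <- tryCatch(measure_ap(tr, beat = 2), error = function(e) NULL)
    if (is.null(m) || is.na(m$apd90))
      tibble::tibble(s2 = s2, apd90 = NA_real_, captured = FALSE)
    else tibble::tibble(s2 = s2, apd90 = m$apd90, captured = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("restitution_curve", class(out))
  out
}
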