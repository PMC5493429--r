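#' Specification for synthetic voltage-clamp data
#'
#' Describes how to generate synthetic whole-cell clamp recordings with known
#' ground truth, emulating experimental Kv1.5 recordings: a truth channel
#' model, additive per-sample Gaussian recording noise, an optional mixture of
#' fast and slow activation kinetics (experimental traces show two activation
#' phenotypes across cells; the channel model itself uses their weighted
#' mean), and an optional linear leak.
#'
#' @param truth An [ikur_model()] holding the ground-truth parameters.
#' @param noise_sd Standard deviation of additive Gaussian noise, pA/pF.
#' @param fast_slow Either `NULL` (no mixture) or a list with elements
#'   `fast`, `slow` (multiplicative scalings of the activation time constant;
#'   defaults 0.5 and 2) and `w` (weight of the fast component, in \[0, 1\]).
#' @param leak_conductance Linear leak conductance, nS/pF (leak reversal
#'   0 mV).
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return An object of class `clamp_data_spec`.
#' @export
clamp_data_spec <- function(truth = ikur_model(), noise_sd = 0,
                            fast_slow = NULL, leak_conductance = 0,
                            seed = 1L) {
  stopifnot(inherits(truth, "ikur_model"), noise_sd >= 0,
            leak_conductance >= 0)
  if (!is.null(fast_slow)) {
    fast_slow <- utils::modifyList(list(fast = 0.5, slow = 2, w = 0.5),
                                   fast_slow)
    stopifnot(fast_slow$w >= 0, fast_slow$w <= 1,
              fast_slow$fast > 0, fast_slow$slow > 0)
  }
  structure(
    list(truth = truth, noise_sd = noise_sd, fast_slow = fast_slow,
         leak_conductance = leak_conductance, seed = as.integer(seed)),
    class = "clamp_data_spec"
  )
}

# Evaluate code with a temporary RNG state so generation is reproducible
# without disturbing the caller's random stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

scale_tau_act <- function(model, factor) {
  model$tau_act_scale <- model$tau_act_scale * factor
  model
}

#' Generate synthetic clamp traces with known ground truth
#'
#' With zero noise, no leak and no fast/slow mixture the output is identical
#' to [simulate_voltage_clamp()].  A fast/slow mixture sums
#' `w * I_fast + (1 - w) * I_slow`, the two components differing only in
#' their activation time constants.
#'
#' @param spec A [clamp_data_spec()].
#' @param protocol A [clamp_protocol()].
#' @param e_k Potassium reversal potential, mV.
#' @inheritParams simulate_voltage_clamp
#' @return A list with `traces`, `iv` (as [simulate_voltage_clamp()]) and
#'   `truth` (the generating spec, for sidecar serialisation).
#' @export
generate_traces <- function(spec, protocol, e_k = -87,
                            mode = c("activation", "availability"),
                            measure = c("end", "peak"), dt_sample = 1) {
  stopifnot(inherits(spec, "clamp_data_spec"))
  mode <- match.arg(mode)
  measure <- match.arg(measure)

  if (is.null(spec$fast_slow)) {
    res <- simulate_voltage_clamp(spec$truth, protocol, e_k, mode, measure,
                                  dt_sample)
  } else {
    fs <- spec$fast_slow
    fast <- simulate_voltage_clamp(scale_tau_act(spec$truth, fs$fast),
                                   protocol, e_k, mode, measure, dt_sample)
    slow <- simulate_voltage_clamp(scale_tau_act(spec$truth, fs$slow),
                                   protocol, e_k, mode, measure, dt_sample)
    res <- fast
    res$traces$current_pA_per_pF <-
      fs$w * fast$traces$current_pA_per_pF +
      (1 - fs$w) * slow$traces$current_pA_per_pF
  }

  tr <- res$traces
  v_at_sample <- if (mode == "activation") tr$step_v_mV
                 else rep(protocol$tail_v, nrow(tr))
  if (spec$leak_conductance > 0)
    tr$current_pA_per_pF <- tr$current_pA_per_pF +
      spec$leak_conductance * v_at_sample
  if (spec$noise_sd > 0)
    tr$current_pA_per_pF <- with_local_seed(
      spec$seed,
      tr$current_pA_per_pF + stats::rnorm(nrow(tr), sd = spec$noise_sd)
    )

  iv <- tr |>
    dplyr::group_by(.data$step_v_mV) |>
    dplyr::summarise(
      current_pA_per_pF = if (measure == "end") {
        .data$current_pA_per_pF[dplyr::n()]
      } else {
        .data$current_pA_per_pF[which.max(abs(.data$current_pA_per_pF))]
      },
      .groups = "drop"
    )
  list(traces = tr, iv = iv, truth = spec)
}

#' Extract normalised steady-state activation/inactivation points
#'
#' Reduces clamp traces to the (voltage, fraction) sample tables that
#' Boltzmann fitting consumes.
#'
#' Two correction modes are offered.  `"none"` is the standard experimental
#' analysis: activation points are end-of-step conductances
#' \eqn{I/(V - E_K)} normalised to the maximum conductance estimate (the
#' maximal-step point is 1 by construction), and availability points are
#' test-pulse peak currents normalised to the maximal test-pulse current.
#' This estimate is contaminated by slow inactivation during the step and by
#' the voltage dependence of the maximal conductance, exactly as real
#' recordings are.  `"truth"` (available only for synthetic data, where the
#' generating model is known) divides out the conductance shape and the other
#' gate's closed-form time course, yielding the exact steady-state gate
#' values; this mode exists so that fitting-stage tests can separate fitting
#' error from extraction bias.
#'
#' @param clamp Result of [generate_traces()] or [simulate_voltage_clamp()]
#'   run in `"activation"` or `"availability"` mode (see `arm`).
#' @param arm `"activation"` or `"availability"` - which protocol arm the
#'   traces came from.
#' @param protocol The [clamp_protocol()] used to generate the traces.
#' @param e_k Potassium reversal potential used in generation, mV.
#' @param correction `"none"` or `"truth"` (see Details).
#' @param truth Truth [ikur_model()] (required for `correction = "truth"`;
#'   taken from `clamp$truth` when present).
#' @param t_read Read-out time within the test pulse for truth-corrected
#'   availability, ms.
#' @return A tibble with columns `v_mV`, `fraction`, plus attribute
#'   `g_max` (the maximum conductance estimate, nS/pF).
#' @export
steady_state_points <- function(clamp, arm = c("activation", "availability"),
                                protocol, e_k = -87,
                                correction = c("none", "truth"),
                                truth = NULL, t_read = 50) {
  arm <- match.arg(arm)
  correction <- match.arg(correction)
  tr <- clamp$traces
  if (nrow(tr) == 0) stop("empty trace set")
  if (correction == "truth" && is.null(truth)) {
    truth <- if (!is.null(clamp$truth)) clamp$truth$truth else NULL
    if (is.null(truth))
      stop("truth model required for correction = 'truth'")
  }

  ends <- tr |>
    dplyr::group_by(.data$step_v_mV) |>
    dplyr::summarise(
      i_end = .data$current_pA_per_pF[dplyr::n()],
      i_peak = max(abs(.data$current_pA_per_pF)),
      .groups = "drop"
    )

  if (arm == "activation") {
    if (correction == "none") {
      g <- ends$i_end / (ends$step_v_mV - e_k)
      if (!any(is.finite(g)) || max(abs(g[is.finite(g)])) == 0)
        stop("zero maximal current; cannot normalise")
      out <- tibble::tibble(v_mV = ends$step_v_mV, fraction = g / max(g))
      attr(out, "g_max") <- max(g)
      return(out)
    }
    # truth mode: divide out conductance shape and the inactivation gate's
    # closed-form time course, leaving the activation gate exactly
    a0 <- activation_steady_state(protocol$holding_v, truth)
    i0 <- inactivation_steady_state(protocol$holding_v, truth)
    gates <- relax_gates(protocol$step_duration, ends$step_v_mV, a0, i0, truth)
    denom <- conductance_scale(ends$step_v_mV, truth) * gates$i *
      (ends$step_v_mV - e_k)
    if (any(denom == 0)) stop("zero denominator in truth correction")
    frac <- ends$i_end / denom
    out <- tibble::tibble(v_mV = ends$step_v_mV, fraction = frac)
    # conductance estimated at the most depolarised steps, where the gate
    # denominators are large and recording noise is not amplified
    gv <- ends$i_end / (gates$a * gates$i * (ends$step_v_mV - e_k))
    top <- order(ends$step_v_mV, decreasing = TRUE)[1:min(3, nrow(ends))]
    attr(out, "g_max") <- mean(gv[top])
    return(out)
  }

  # availability arm: traces are the test pulses after conditioning at each
  # step_v_mV
  if (correction == "none") {
    if (max(ends$i_peak) == 0) stop("zero maximal current; cannot normalise")
    out <- tibble::tibble(v_mV = ends$step_v_mV,
                          fraction = ends$i_peak / max(ends$i_peak))
    attr(out, "g_max") <- max(ends$i_peak) / (protocol$tail_v - e_k)
    return(out)
  }
  # truth mode: read the test pulse at a fixed time, divide out the
  # activation gate's closed-form course, and propagate the inactivation
  # gate back to the start of the test pulse
  vt <- protocol$tail_v
  a0 <- activation_steady_state(protocol$holding_v, truth)
  i0 <- inactivation_steady_state(protocol$holding_v, truth)
  cond <- relax_gates(protocol$step_duration, ends$step_v_mV, a0, i0, truth)
  read <- vapply(seq_len(nrow(ends)), function(j) {
    v_c <- ends$step_v_mV[j]
    sw <- tr[tr$step_v_mV == v_c, ]
    k <- which.min(abs(sw$time_ms - t_read))
    tk <- sw$time_ms[k]
    a_inf_t <- activation_steady_state(vt, truth)
    a_tk <- a_inf_t + (cond$a[j] - a_inf_t) * exp(-tk / tau_activation(vt, truth))
    i_tk <- sw$current_pA_per_pF[k] /
      (conductance_scale(vt, truth) * a_tk * (vt - e_k))
    i_inf_t <- inactivation_steady_state(vt, truth)
    i_inf_t + (i_tk - i_inf_t) * exp(tk / tau_inactivation(vt, truth))
  }, numeric(1))
  out <- tibble::tibble(v_mV = ends$step_v_mV, fraction = read)
  attr(out, "g_max") <- max(ends$i_peak) / (vt - e_k)
  out
}
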