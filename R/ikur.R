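#' The I_Kur channel model
#'
#' Constructs the wild-type (WT) formulation of the atrial ultra-rapid
#' delayed rectifier current I_Kur (Kv1.5, gene *KCNA5*), or retrieves one of
#' the six naturally occurring variants via [apply_mutant()].
#'
#' The WT model consists of
#' * a steady-state activation curve that is the product of two Boltzmann
#'   factors (half-voltages -17.67 and -8.45 mV, slopes -5.75 and -11.51 mV),
#' * a steady-state inactivation curve with amplitude 0.52, half-voltage
#'   15.11 mV, slope 7.57 mV and a minimum-availability floor of 0.46,
#' * voltage-dependent activation and inactivation time constants, each
#'   divided by a Q10 temperature-correction factor of 3.52 (experiments at
#'   room temperature, simulations at body temperature),
#' * a voltage-dependent maximal conductance
#'   \eqn{g(V) = 0.64\,[4.51 + 1.90/(1+\exp((V-20.52)/-8.27))]} (nS/pF).
#'
#' The current is \eqn{I_{Kur} = g(V)\, a\, i\, (V - E_K)} in pA/pF, with
#' activation gate \eqn{a} and inactivation gate \eqn{i} relaxing
#' first-order toward their steady states.
#'
#' @param label Model label; `"WT"` builds the wild-type channel.
#' @return An object of class `ikur_model`.
#' @seealso [apply_mutant()], [kcna5_variants()], [simulate_voltage_clamp()]
#' @examples
#' wt <- ikur_model()
#' activation_steady_state(c(-40, 0, 40), wt)
#' @export
ikur_model <- function(label = "WT") {
  structure(
    list(
      label = label,
      act_ss = list(
        boltzmann_params(-17.67, -5.75),
        boltzmann_params(-8.45, -11.51)
      ),
      inact_ss = boltzmann_params(15.11, 7.57, amplitude = 0.52,
                                  floor_ma = 0.46),
      tau_act_params = c(a1 = 45.67, v1 = 11.23, k1 = 11.53, c1 = 4.27,
                         a2 = 0.26, v2 = 35.87, k2 = -3.88, c2 = 0.29),
      tau_inact_params = c(a = 2328, v = 9.44, k = 3.58, c = 1739.14),
      kq10 = 3.52,
      g_params = c(scale = 0.64, g_base = 4.51, g_amp = 1.90,
                   v_half = 20.52, slope = -8.27),
      g_factor = 1,
      tau_act_scale = 1
    ),
    class = "ikur_model"
  )
}

#' @export
print.ikur_model <- function(x, ...) {
  cat(sprintf("<ikur_model> %s (g_factor = %.3g, KQ10 = %.2f)\n",
              x$label, x$g_factor, x$kq10))
  invisible(x)
}

#' Steady-state activation of I_Kur
#'
#' For the WT model this is the product of two Boltzmann factors; variant
#' models built by [apply_mutant()] carry a single shifted Boltzmann.
#'
#' @param v Membrane voltage(s), mV.
#' @param model An [ikur_model()].
#' @return Activation gating variable at steady state, in \[0, 1\].
#' @export
activation_steady_state <- function(v, model) {
  Reduce(`*`, lapply(model$act_ss, function(b) boltzmann(v, b)))
}

#' Steady-state inactivation (availability) of I_Kur
#'
#' Bounded below by the minimum availability (MA): the fraction of channels
#' that remain available at strongly depolarised potentials.
#'
#' @inheritParams activation_steady_state
#' @return Inactivation gating variable at steady state.
#' @export
inactivation_steady_state <- function(v, model) {
  boltzmann(v, model$inact_ss)
}

#' Activation time constant (ms), Q10-corrected
#'
#' The product of two voltage-dependent sigmoid brackets, divided by the
#' Q10 factor so that kinetics measured at room temperature apply at
#' physiological temperature.
#'
#' @inheritParams activation_steady_state
#' @export
tau_activation <- function(v, model) {
  p <- model$tau_act_params
  raw <- (p[["a1"]] / (1 + exp((v + p[["v1"]]) / p[["k1"]])) + p[["c1"]]) *
    (p[["a2"]] / (1 + exp((v + p[["v2"]]) / p[["k2"]])) + p[["c2"]])
  scale <- if (is.null(model$tau_act_scale)) 1 else model$tau_act_scale
  raw * scale / model$kq10
}

#' Inactivation time constant (ms), Q10-corrected
#'
#' @inheritParams activation_steady_state
#' @export
tau_inactivation <- function(v, model) {
  p <- model$tau_inact_params
  raw <- p[["a"]] / (1 + exp((v - p[["v"]]) / p[["k"]])) + p[["c"]]
  raw / model$kq10
}

#' Voltage-dependent maximal conductance of I_Kur (nS/pF)
#'
#' The channel conductivity depends explicitly on membrane voltage,
#' saturating between its hyperpolarised and depolarised plateaus; variant
#' channels scale it by their conductance factor.
#'
#' @inheritParams activation_steady_state
#' @export
conductance_scale <- function(v, model) {
  g <- model$g_params
  model$g_factor * g[["scale"]] *
    (g[["g_base"]] + g[["g_amp"]] /
       (1 + exp((v - g[["v_half"]]) / g[["slope"]])))
}

#' Instantaneous I_Kur current density (pA/pF)
#'
#' @param v Membrane voltage, mV.
#' @param a Activation gate value in \[0, 1\].
#' @param i Inactivation gate value in \[0, 1\].
#' @param e_k Potassium reversal potential, mV.
#' @param model An [ikur_model()].
#' @export
ikur_current <- function(v, a, i, e_k, model) {
  conductance_scale(v, model) * a * i * (v - e_k)
}

#' Advance the I_Kur gates by one time step (Rush-Larsen)
#'
#' At fixed voltage each Hodgkin-Huxley gate relaxes exponentially toward its
#' steady state; the update is therefore exact for any step size:
#' \eqn{a(t+dt) = a_\infty + (a - a_\infty) e^{-dt/\tau_a}}.
#'
#' @param state Numeric vector `c(a, i)` of current gate values.
#' @param v Membrane voltage held over the step, mV.
#' @param dt Step size, ms (must be >= 0).
#' @param model An [ikur_model()].
#' @return Updated `c(a, i)`.
#' @export
step_gates <- function(state, v, dt, model) {
  stopifnot(dt >= 0)
  a_inf <- activation_steady_state(v, model)
  i_inf <- inactivation_steady_state(v, model)
  c(
    a_inf + (state[[1]] - a_inf) * exp(-dt / tau_activation(v, model)),
    i_inf + (state[[2]] - i_inf) * exp(-dt / tau_inactivation(v, model))
  )
}

# ---- variants ---------------------------------------------------------------

#' The six KCNA5 variant parameter changes
#'
#' Relative changes of each mutant channel with respect to WT: additive
#' half-voltage shifts (mV), multiplicative slope-factor changes, an additive
#' change to the minimum availability (MA) of inactivation, and a
#' multiplicative maximal-conductance factor.  Activation/inactivation kinetics
#' (time constants) are unchanged by the variants.
#'
#' D332H, A305T and E48G are gain-of-function; Y155C, D469E and P488S are
#' loss-of-function.  "D322H" is accepted as an alias for D332H (both spellings
#' circulate in the literature describing these variants).
#'
#' @return A tibble with one row per variant and columns
#'   `mutation`, `class`, `d_vhalf_act`, `k_act_factor`, `d_vhalf_inact`,
#'   `k_inact_factor`, `d_ma`, `g_factor`.
#' @export
kcna5_variants <- function() {
  tibble::tribble(
    ~mutation, ~class, ~d_vhalf_act, ~k_act_factor, ~d_vhalf_inact,
    ~k_inact_factor, ~d_ma, ~g_factor,
    "D332H", "gain", -3.264, 0.809,  9.615, 0.801,  0.074, 1.799,
    "E48G",  "gain", -3.024, 0.956,  4.028, 0.940,  0.039, 1.323,
    "A305T", "gain", -4.068, 1.101,  6.032, 0.748,  0.071, 1.445,
    "Y155C", "loss", -0.893, 0.757,  5.013, 0.782,  0.035, 0.475,
    "D469E", "loss",  0.000, 1.000,  4.545, 0.842, -0.093, 0.546,
    "P488S", "loss",  0.000, 0.834, -1.415, 0.688, -0.110, 0.038
  )
}

#' Construct a variant parameter-change record
#'
#' @param d_vhalf_act,d_vhalf_inact Additive half-voltage shifts, mV.
#' @param k_act_factor,k_inact_factor Multiplicative slope-factor changes
#'   (must be positive).
#' @param d_ma Additive change to minimum availability.
#' @param g_factor Multiplicative conductance factor (>= 0).
#' @return An object of class `mutant_delta`.
#' @export
mutant_delta <- function(d_vhalf_act = 0, k_act_factor = 1,
                         d_vhalf_inact = 0, k_inact_factor = 1,
                         d_ma = 0, g_factor = 1) {
  if (k_act_factor <= 0 || k_inact_factor <= 0)
    stop("slope factors must be positive")
  if (g_factor < 0) stop("g_factor must be non-negative")
  structure(
    list(d_vhalf_act = d_vhalf_act, k_act_factor = k_act_factor,
         d_vhalf_inact = d_vhalf_inact, k_inact_factor = k_inact_factor,
         d_ma = d_ma, g_factor = g_factor),
    class = "mutant_delta"
  )
}

#' Look up a variant's parameter changes by name
#'
#' @param mutation Variant name (e.g. `"D469E"`); `"D322H"` is accepted as an
#'   alias for D332H, and `"WT"` returns the identity record.
#' @return A `mutant_delta`.
#' @export
variant_delta <- function(mutation) {
  mutation <- canonical_mutation(mutation)
  if (mutation == "WT") return(mutant_delta())
  tab <- kcna5_variants()
  row <- tab[tab$mutation == mutation, ]
  if (nrow(row) != 1)
    stop("unknown mutation: ", mutation, " (known: WT, ",
         paste(tab$mutation, collapse = ", "), ")")
  mutant_delta(row$d_vhalf_act, row$k_act_factor, row$d_vhalf_inact,
               row$k_inact_factor, row$d_ma, row$g_factor)
}

canonical_mutation <- function(mutation) {
  stopifnot(is.character(mutation), length(mutation) == 1)
  if (identical(toupper(mutation), "D322H")) return("D332H")
  toupper(mutation)
}

# Cache for the WT-equivalent single-Boltzmann activation fit.
.ikursim_cache <- new.env(parent = emptyenv())

#' WT-equivalent single-Boltzmann activation parameters
#'
#' The WT activation curve is a product of two Boltzmann factors, but variant
#' parameter changes are expressed relative to single-Boltzmann fits.  This
#' returns the least-squares single-Boltzmann approximation of the WT product
#' over the voltage-clamp range -60..+60 mV, which serves as the baseline to
#' which variant shifts are applied.
#'
#' @return A [boltzmann_params()] with amplitude 1 and floor 0.
#' @export
wt_equivalent_activation <- function() {
  if (!is.null(.ikursim_cache$wt_eq_act)) return(.ikursim_cache$wt_eq_act)
  wt <- ikur_model()
  v <- seq(-60, 60, by = 1)
  y <- activation_steady_state(v, wt)
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + exp((v - vh) / k)),
    start = list(vh = -12, k = -8),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  est <- stats::coef(fit)
  out <- boltzmann_params(unname(est[["vh"]]), unname(est[["k"]]))
  .ikursim_cache$wt_eq_act <- out
  out
}

#' Build a variant I_Kur model from WT-relative parameter changes
#'
#' Applies a [mutant_delta()] to the WT channel: half-voltages are shifted
#' additively, slope factors multiplied, the minimum availability shifted
#' additively (clipped into \[0, 1)), and the maximal conductance scaled.
#' Time constants are copied from WT unchanged, as the variants do not alter
#' channel kinetics.  Activation uses the WT-equivalent single Boltzmann
#' ([wt_equivalent_activation()]) as baseline; the inactivation ceiling
#' (availability at hyperpolarised potentials, 0.98 for WT) is preserved, so
#' the amplitude absorbs the MA change.
#'
#' @param delta A [mutant_delta()] or a variant name understood by
#'   [variant_delta()].
#' @param label Label for the resulting model; defaults to the variant name
#'   when `delta` is a name.
#' @return An `ikur_model`.
#' @examples
#' d469e <- apply_mutant("D469E")
#' conductance_scale(0, d469e) / conductance_scale(0, ikur_model())
#' @export
apply_mutant <- function(delta, label = NULL) {
  if (is.character(delta)) {
    if (is.null(label)) label <- canonical_mutation(delta)
    delta <- variant_delta(delta)
  }
  stopifnot(inherits(delta, "mutant_delta"))
  if (is.null(label)) label <- "variant"
  wt <- ikur_model()
  act0 <- wt_equivalent_activation()
  inact0 <- wt$inact_ss
  ceiling0 <- inact0$amplitude + inact0$floor_ma
  ma <- min(max(inact0$floor_ma + delta$d_ma, 0), 1 - 1e-9)
  model <- wt
  model$label <- label
  model$act_ss <- list(boltzmann_params(
    act0$v_half + delta$d_vhalf_act,
    act0$slope_k * delta$k_act_factor
  ))
  model$inact_ss <- boltzmann_params(
    inact0$v_half + delta$d_vhalf_inact,
    inact0$slope_k * delta$k_inact_factor,
    amplitude = ceiling0 - ma,
    floor_ma = ma
  )
  model$g_factor <- wt$g_factor * delta$g_factor
  model
}
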