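#' Boltzmann curve parameters
#'
#' A Boltzmann sigmoid as used throughout voltage-clamp electrophysiology:
#' \deqn{B(V) = \frac{A}{1 + \exp[(V - V_{1/2})/k]} + MA}
#' where \eqn{V_{1/2}} is the half-(in)activation voltage, \eqn{k} the slope
#' factor (negative for curves that rise with depolarisation, positive for
#' curves that fall), \eqn{A} the amplitude and \eqn{MA} the floor.  For
#' steady-state inactivation of I_Kur the floor is the *minimum availability*:
#' the fraction of channels that never inactivate at depolarised potentials.
#'
#' @param v_half Half-activation voltage (mV).
#' @param slope_k Slope factor (mV); must be non-zero.
#' @param amplitude Amplitude of the sigmoid component, in (0, 1].
#' @param floor_ma Floor (minimum availability), in \[0, 1).
#'
#' @return An object of class `boltzmann_params`.
#' @examples
#' bp <- boltzmann_params(-10, -6)
#' boltzmann(seq(-60, 40, 10), bp)
#' @export
boltzmann_params <- function(v_half, slope_k, amplitude = 1, floor_ma = 0) {
  stopifnot(is.finite(v_half), is.finite(slope_k), is.finite(amplitude),
            is.finite(floor_ma))
  if (slope_k == 0) stop("slope_k must be non-zero")
  if (floor_ma < 0 || floor_ma >= 1) stop("floor_ma must be in [0, 1)")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must be in (0, 1]")
  if (amplitude + floor_ma > 1 + 1e-9)
    stop("amplitude + floor_ma must not exceed 1")
  structure(
    list(v_half = v_half, slope_k = slope_k, amplitude = amplitude,
         floor_ma = floor_ma),
    class = "boltzmann_params"
  )
}

#' Evaluate a Boltzmann curve
#'
#' @param v Voltage(s), mV.
#' @param params A [boltzmann_params()] object.
#' @return Numeric vector of the same length as `v`.
#' @export
boltzmann <- function(v, params) {
  params$amplitude / (1 + exp((v - params$v_half) / params$slope_k)) +
    params$floor_ma
}

#' @export
print.boltzmann_params <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_params> V1/2 = %.3f mV, k = %.3f mV, A = %.3f, floor = %.3f\n",
    x$v_half, x$slope_k, x$amplitude, x$floor_ma))
  invisible(x)
}
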