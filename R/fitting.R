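#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

new_boltzmann_fit <- function(params, rss, n_points, converged = TRUE,
                              unidentifiable = character()) {
  structure(
    list(params = params, rss = rss, n_points = n_points,
         converged = converged, unidentifiable = unidentifiable),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> V1/2 = %.4f mV, k = %.4f mV, A = %.4f, floor = %.4f\n",
    x$params$v_half, x$params$slope_k, x$params$amplitude,
    x$params$floor_ma))
  cat(sprintf("  rss = %.3g over %d points%s\n", x$rss, x$n_points,
              if (length(x$unidentifiable))
                paste0(" (unidentifiable: ",
                       paste(x$unidentifiable, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' @rdname fit_boltzmann_activation
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(
    term = c("v_half", "slope_k", "amplitude", "floor_ma"),
    estimate = c(x$params$v_half, x$params$slope_k, x$params$amplitude,
                 x$params$floor_ma)
  )
}

#' @rdname fit_boltzmann_activation
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points,
                 converged = x$converged,
                 n_unidentifiable = length(x$unidentifiable))
}

as_points <- function(points) {
  df <- as.data.frame(points)
  if (all(c("v_mV", "fraction") %in% names(df)))
    df <- df[, c("v_mV", "fraction")]
  names(df) <- c("v", "y")
  df <- df[is.finite(df$v) & is.finite(df$y), ]
  if (nrow(df) == 0) stop("no finite points to fit")
  df
}

# Bounded multi-start Levenberg-Marquardt least squares.  Sigmoid fits have
# local minima; each start is run to tight tolerance and the lowest-RSS
# converged solution wins.
multistart_nls <- function(df, formula, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        formula, data = df, start = s, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Boltzmann fit failed to converge from any start")
  best
}

#' Fit Boltzmann steady-state curves to clamp-derived points
#'
#' `fit_boltzmann_activation()` fits the normalised activation form
#' \eqn{y = 1/\{1 + \exp[(V - V_{1/2})/k]\}} (amplitude fixed at 1, floor at
#' 0).  `fit_boltzmann_inactivation()` fits the availability form
#' \eqn{y = A/\{1 + \exp[(V - V_{1/2})/k]\} + MA}; in the default
#' `normalised` mode the amplitude is tied to the floor (\eqn{A = 1 - MA},
#' the conventional normalised form), while `normalised = FALSE` frees the
#' amplitude (appropriate when the availability ceiling is itself below 1).
#'
#' Fitting uses bounded Levenberg-Marquardt least squares with multiple
#' starting points drawn from a coarse grid, to tolerance 1e-15, so exact
#' synthetic inputs are recovered to near machine precision.  Flat
#' (floor-only) availability data yields `floor_ma` equal to the mean with
#' `v_half`/`slope_k` flagged unidentifiable (a warning, not an error).
#'
#' @param points A data frame or tibble of points: columns `v_mV` and
#'   `fraction` (or any two columns taken as voltage and fraction).
#' @param normalised For inactivation: tie amplitude to `1 - floor_ma`?
#' @return A `boltzmann_fit` (see [tidy()]/[glance()] methods).
#' @examples
#' v <- seq(-60, 20, 10)
#' pts <- tibble::tibble(v_mV = v,
#'                       fraction = boltzmann(v, boltzmann_params(-10, -6)))
#' tidy(fit_boltzmann_activation(pts))
#' @export
fit_boltzmann_activation <- function(points) {
  df <- as_points(points)
  if (nrow(df) < 4) stop("need at least 4 points spanning the transition")
  if (stats::sd(df$y) == 0) stop("degenerate input: all points equal")
  vh0 <- df$v[which.min(abs(df$y - 0.5))]
  starts <- lapply(c(-3, -6, -10, -15, -25),
                   function(k) list(vh = vh0, k = k))
  best <- multistart_nls(
    df, y ~ 1 / (1 + exp((v - vh) / k)), starts,
    lower = c(vh = -150, k = -100), upper = c(vh = 100, k = -0.1)
  )
  est <- stats::coef(best$fit)
  new_boltzmann_fit(
    boltzmann_params(unname(est[["vh"]]), unname(est[["k"]])),
    best$rss, nrow(df)
  )
}

#' @rdname fit_boltzmann_activation
#' @export
fit_boltzmann_inactivation <- function(points, normalised = TRUE) {
  df <- as_points(points)
  if (nrow(df) < 5)
    stop("need at least 5 points including the depolarised floor")
  if (stats::sd(df$y) < 1e-12) {
    warning("flat availability data: v_half and slope_k unidentifiable")
    return(new_boltzmann_fit(
      boltzmann_params(0, 10, amplitude = 1e-12,
                       floor_ma = min(max(mean(df$y), 0), 1 - 1e-9)),
      sum((df$y - mean(df$y))^2), nrow(df),
      unidentifiable = c("v_half", "slope_k")
    ))
  }
  vh0 <- df$v[which.min(abs(df$y - (max(df$y) + min(df$y)) / 2))]
  ma0 <- max(min(df$y), 0)
  starts <- lapply(c(3, 6, 10, 15, 25), function(k)
    if (normalised) list(vh = vh0, k = k, ma = ma0)
    else list(vh = vh0, k = k, ma = ma0,
              amp = max(min(max(df$y) - min(df$y), 1 - ma0), 1e-3)))
  if (normalised) {
    best <- multistart_nls(
      df, y ~ (1 - ma) / (1 + exp((v - vh) / k)) + ma, starts,
      lower = c(vh = -150, k = 0.1, ma = 0),
      upper = c(vh = 100, k = 100, ma = 1 - 1e-9)
    )
    est <- stats::coef(best$fit)
    params <- boltzmann_params(unname(est[["vh"]]), unname(est[["k"]]),
                               amplitude = 1 - unname(est[["ma"]]),
                               floor_ma = unname(est[["ma"]]))
  } else {
    best <- multistart_nls(
      df, y ~ amp / (1 + exp((v - vh) / k)) + ma, starts,
      lower = c(vh = -150, k = 0.1, ma = 0, amp = 1e-9),
      upper = c(vh = 100, k = 100, ma = 1 - 1e-9, amp = 1)
    )
    est <- stats::coef(best$fit)
    ma_hat <- unname(est[["ma"]])
    # noisy data can push amplitude + floor marginally past full
    # availability; clamp to the physical bound
    amp_hat <- min(unname(est[["amp"]]), 1 - ma_hat)
    params <- boltzmann_params(unname(est[["vh"]]), unname(est[["k"]]),
                               amplitude = max(amp_hat, 1e-9),
                               floor_ma = ma_hat)
  }
  new_boltzmann_fit(params, best$rss, nrow(df))
}

#' Locate the activation-phase fitting window of a trace
#'
#' Returns the time window in which the current has completed between `lo`
#' and `hi` of its total rise, avoiding the stimulus edge and late
#' slow-inactivation contamination.
#'
#' @param trace A tibble with columns `time_ms` and `current_pA_per_pF`.
#' @param lo,hi Fractions of the total rise delimiting the window.
#' @return `c(t_lo, t_hi)` in ms.
#' @export
activation_window <- function(trace, lo = 0.05, hi = 0.95) {
  cur <- trace$current_pA_per_pF
  rise <- (cur - cur[1]) / (max(cur) - cur[1])
  i_lo <- which(rise >= lo)[1]
  i_hi <- which(rise >= hi)[1]
  c(trace$time_ms[i_lo], trace$time_ms[i_hi])
}

#' Fit a mono-exponential time constant to a trace segment
#'
#' Fits \eqn{A(1 - e^{-t/\tau}) + C} to a rising (activating) segment or
#' \eqn{A e^{-t/\tau} + C} to a decaying one, by bounded multi-start least
#' squares.  The direction is inferred from the segment unless given.
#'
#' @param trace A tibble with columns `time_ms` and `current_pA_per_pF`.
#' @param window `c(t0, t1)` (ms) delimiting the fitted segment; see
#'   [activation_window()].
#' @param type `"auto"`, `"rise"` or `"decay"`.
#' @return Fitted time constant, ms.
#' @export
fit_monoexp_tau <- function(trace, window = activation_window(trace),
                            type = c("auto", "rise", "decay")) {
  type <- match.arg(type)
  seg <- trace[trace$time_ms >= window[1] & trace$time_ms <= window[2], ]
  if (nrow(seg) < 4) stop("window contains fewer than 4 samples")
  t <- seg$time_ms - seg$time_ms[1]
  y <- seg$current_pA_per_pF
  # require a clearly monotone segment: coarse bin means must be ordered
  nb <- min(5, nrow(seg))
  bins <- tapply(y, cut(seq_along(y), nb), mean)
  d <- diff(bins)
  if (!(all(d >= 0) || all(d <= 0)))
    stop("current is not monotone within the fitting window")
  rising <- if (type == "auto") y[length(y)] > y[1] else type == "rise"
  span <- window[2] - window[1]
  df <- data.frame(t = t, y = y)
  form <- if (rising) y ~ A * (1 - exp(-t / tau)) + C
          else y ~ A * exp(-t / tau) + C
  amp0 <- y[length(y)] - y[1]
  starts <- lapply(span * c(0.05, 0.2, 0.5, 1),
                   function(tau0) if (rising)
                     list(A = amp0, C = y[1], tau = tau0)
                   else list(A = -amp0, C = y[length(y)], tau = tau0))
  best <- multistart_nls(df, form, starts,
                         lower = c(A = -Inf, C = -Inf, tau = 1e-6),
                         upper = c(A = Inf, C = Inf, tau = Inf))
  unname(stats::coef(best$fit)[["tau"]])
}

#' Q10 temperature correction of a time constant
#'
#' Divides a time constant measured at room temperature by the Q10 factor to
#' obtain its value at physiological temperature.
#'
#' @param tau_experimental Time constant, ms (> 0).
#' @param kq10 Q10 factor (> 0); 3.52 for I_Kur here.
#' @return Corrected time constant, ms.
#' @export
apply_q10 <- function(tau_experimental, kq10) {
  stopifnot(all(tau_experimental > 0), kq10 > 0)
  tau_experimental / kq10
}

#' Derive WT-relative parameter changes from two fitted channels
#'
#' The inverse of [apply_mutant()]: given fitted activation/inactivation
#' Boltzmann curves and maximum-conductance estimates for a reference (WT)
#' channel and a variant, returns the additive half-voltage and
#' minimum-availability differences and the multiplicative slope and
#' conductance ratios.
#'
#' @param wt,mut Lists with elements `act` (a `boltzmann_fit`), `inact`
#'   (a `boltzmann_fit`) and `g` (maximum-conductance estimate).
#' @return A [mutant_delta()].
#' @export
derive_relative_changes <- function(wt, mut) {
  stopifnot(inherits(wt$act, "boltzmann_fit"),
            inherits(wt$inact, "boltzmann_fit"),
            inherits(mut$act, "boltzmann_fit"),
            inherits(mut$inact, "boltzmann_fit"))
  if (wt$act$params$slope_k == 0 || wt$inact$params$slope_k == 0)
    stop("zero WT slope factor")
  if (is.null(wt$g) || wt$g == 0) stop("zero WT conductance estimate")
  mutant_delta(
    d_vhalf_act = mut$act$params$v_half - wt$act$params$v_half,
    k_act_factor = mut$act$params$slope_k / wt$act$params$slope_k,
    d_vhalf_inact = mut$inact$params$v_half - wt$inact$params$v_half,
    k_inact_factor = mut$inact$params$slope_k / wt$inact$params$slope_k,
    d_ma = mut$inact$params$floor_ma - wt$inact$params$floor_ma,
    g_factor = mut$g / wt$g
  )
}
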