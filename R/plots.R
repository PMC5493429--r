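#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an action-potential or clamp trace
#'
#' @param trace A tibble from [pace()] (columns `time_ms`, `v_mV`) or a
#'   clamp trace (`time_ms`, `current_pA_per_pF`, coloured by `step_v_mV`).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  if ("v_mV" %in% names(trace)) {
    ggplot2::ggplot(trace, ggplot2::aes(.data$time_ms, .data$v_mV)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (ms)", y = "membrane voltage (mV)")
  } else {
    ggplot2::ggplot(trace,
                    ggplot2::aes(.data$time_ms, .data$current_pA_per_pF,
                                 colour = factor(.data$step_v_mV))) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (ms)", y = "current (pA/pF)",
                    colour = "step (mV)")
  }
}

#' @rdname plot_trace
#' @param object,... Method arguments.
#' @export
autoplot.cable_spacetime <- function(object, ...) {
  df <- tidyr::expand_grid(
    time_ms = object$time,
    node = seq_len(ncol(object$v))
  )
  df <- dplyr::arrange(df, .data$node, .data$time_ms)
  df$v_mV <- as.vector(object$v)
  df$x_mm <- (df$node - 1) * object$config$dx
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$x_mm,
                                   fill = .data$v_mV)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "V (mV)") +
    ggplot2::labs(x = "time (ms)", y = "position (mm)")
}

#' @rdname plot_trace
#' @export
autoplot.restitution_curve <- function(object, ...) {
  ggplot2::ggplot(object[object$captured, ],
                  ggplot2::aes(.data$s2, .data$apd90)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "S2 coupling interval (ms)", y = "APD90 (ms)")
}

#' @rdname plot_trace
#' @export
autoplot.reentry_metrics <- function(object, ...) {
  tr <- attr(object, "site_traces")
  t <- attr(object, "time")
  df <- tidyr::expand_grid(site = seq_len(ncol(tr)), time_ms = t)
  df <- dplyr::arrange(df, .data$site, .data$time_ms)
  df$v_mV <- as.vector(tr)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$v_mV)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = "time (ms)", y = "V (mV)")
}

#' Plot steady-state curves of I_Kur models
#'
#' Overlays steady-state activation and inactivation (availability) curves
#' of one or more channel models over a voltage range.
#'
#' @param models A named list of [ikur_model()] objects.
#' @param v Voltage grid, mV.
#' @return A ggplot object.
#' @export
plot_steady_states <- function(models, v = seq(-80, 60, 0.5)) {
  if (inherits(models, "ikur_model")) models <- list(model = models)
  df <- dplyr::bind_rows(lapply(names(models), function(nm) {
    dplyr::bind_rows(
      tibble::tibble(model = nm, curve = "activation", v_mV = v,
                     fraction = activation_steady_state(v, models[[nm]])),
      tibble::tibble(model = nm, curve = "inactivation", v_mV = v,
                     fraction = inactivation_steady_state(v, models[[nm]]))
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$v_mV, .data$fraction,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(x = "voltage (mV)", y = "steady-state fraction")
}
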