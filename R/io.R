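#' Write clamp or AP traces to CSV
#'
#' Trace tables are written with their standard columns (`step_v_mV`,
#' `time_ms`, `current_pA_per_pF` for clamp traces; `time_ms`, `v_mV` for
#' voltage traces).
#'
#' @param trace A trace tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Serialise an I_Kur model parameter set to JSON
#'
#' Parameters are keyed by their conventional symbols (V1/2, k, amplitude,
#' floor/minimum availability, Q10, conductance constants).
#'
#' @param model An [ikur_model()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
ikur_model_json <- function(model, path = NULL) {
  act <- lapply(model$act_ss, function(b)
    list(v_half = b$v_half, k = b$slope_k))
  rec <- list(
    label = model$label,
    activation = act,
    inactivation = list(v_half = model$inact_ss$v_half,
                        k = model$inact_ss$slope_k,
                        amplitude = model$inact_ss$amplitude,
                        minimum_availability = model$inact_ss$floor_ma),
    tau_activation = as.list(model$tau_act_params),
    tau_inactivation = as.list(model$tau_inact_params),
    kq10 = model$kq10,
    conductance = as.list(model$g_params),
    g_factor = model$g_factor
  )
  if (is.null(path))
    return(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an I_Kur model from its JSON record
#'
#' @param path Path to (or JSON string of) a record written by
#'   [ikur_model_json()].
#' @return An `ikur_model`.
#' @export
ikur_model_from_json <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  m <- ikur_model(label = rec$label)
  m$act_ss <- lapply(rec$activation, function(a)
    boltzmann_params(a$v_half, a$k))
  m$inact_ss <- boltzmann_params(rec$inactivation$v_half,
                                 rec$inactivation$k,
                                 amplitude = rec$inactivation$amplitude,
                                 floor_ma = rec$inactivation$minimum_availability)
  m$kq10 <- rec$kq10
  m$g_factor <- rec$g_factor
  m
}
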