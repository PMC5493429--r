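known_experiments <- c("clamp-fit", "table1-roundtrip", "cell-sim",
                       "restitution", "ead-scan", "strand-cv", "vw-scan",
                       "san-pattern", "reentry-2d")

#' Fit a channel variant from synthetic clamp data
#'
#' Generates synthetic activation and availability protocols from a truth
#' channel, extracts steady-state points, and fits the Boltzmann curves and
#' conductance estimate.  The full pipeline behind the WT-relative change
#' recovery.
#'
#' @param mutation `"WT"` or a variant name; the truth channel is the
#'   corresponding [apply_mutant()] model.
#' @param noise_sd Additive recording noise, pA/pF.
#' @param seed Seed for the noise.
#' @param correction Point-extraction mode (see [steady_state_points()]).
#' @param e_k Potassium reversal potential, mV.
#' @return A list: `act`, `inact` (each a `boltzmann_fit`), `g`.
#' @export
fit_channel_variant <- function(mutation = "WT", noise_sd = 0, seed = 1L,
                                correction = "truth", e_k = -87) {
  truth <- if (identical(canonical_mutation(mutation), "WT"))
    apply_mutant(mutant_delta(), label = "WTeq") else apply_mutant(mutation)
  proto_act <- clamp_protocol(step_voltages = seq(-60, 60, 10),
                              step_duration = 1500)
  proto_av <- clamp_protocol(step_voltages = seq(-100, 60, 10),
                             step_duration = 30000)
  spec <- clamp_data_spec(truth = truth, noise_sd = noise_sd, seed = seed)
  act <- generate_traces(spec, proto_act, e_k = e_k)
  av <- generate_traces(spec, proto_av, e_k = e_k, mode = "availability")
  pa <- steady_state_points(act, "activation", proto_act, e_k = e_k,
                            correction = correction, truth = truth)
  pi <- steady_state_points(av, "availability", proto_av, e_k = e_k,
                            correction = correction, truth = truth)
  list(act = fit_boltzmann_activation(pa),
       inact = fit_boltzmann_inactivation(pi, normalised = FALSE),
       g = attr(pa, "g_max"))
}

#' Generate-fit-difference round trip over all six variants
#'
#' For each variant: synthesise clamp data from its parameter set, fit, and
#' difference against the WT fit, recovering the WT-relative change table.
#'
#' @inheritParams fit_channel_variant
#' @return A tibble with the recovered deltas per mutation and the maximum
#'   absolute error against the built-in variant table.
#' @export
table1_roundtrip <- function(noise_sd = 0, seed = 1L) {
  wt <- fit_channel_variant("WT", noise_sd = noise_sd, seed = seed)
  rows <- lapply(kcna5_variants()$mutation, function(m) {
    mf <- fit_channel_variant(m, noise_sd = noise_sd, seed = seed + 1L)
    d <- derive_relative_changes(wt, mf)
    truth <- variant_delta(m)
    tibble::tibble(
      mutation = m,
      d_vhalf_act = d$d_vhalf_act, k_act_factor = d$k_act_factor,
      d_vhalf_inact = d$d_vhalf_inact, k_inact_factor = d$k_inact_factor,
      d_ma = d$d_ma, g_factor = d$g_factor,
      max_abs_error = max(abs(unlist(d) - unlist(truth)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Acute beta-adrenergic EAD scan across variants and regions
#'
#' For each (mutation, region): pace the drug-free cell to steady state at
#' 1 Hz, then apply the isoprenaline parameter set acutely for `iso_beats`
#' beats (an ISO wash-in) and count EADs on the final beats.
#'
#' @param model_id Cell model lineage.
#' @param mutations,regions Character vectors to scan.
#' @param pre_beats Drug-free conditioning beats.
#' @param iso_beats Beats simulated with ISO applied.
#' @param n_last Report the maximum EAD count over the final `n_last` beats.
#' @param dt Integration step, ms.
#' @return A tibble (`mutation`, `region`, `ead_count`, `has_ead`).
#' @export
ead_scan <- function(model_id = "grandi",
                     mutations = c("WT", "Y155C", "D469E", "P488S"),
                     regions = c("RA", "CT", "PM"), pre_beats = 50,
                     iso_beats = 10, n_last = 2, dt = NULL) {
  rows <- list()
  for (m in mutations) {
    for (r in regions) {
      base <- build_cell(model_id, r, m, caf = FALSE, iso = FALSE)
      if (is.null(dt)) dt <- default_dt(base$code)
      base <- precondition(base, n_beats = pre_beats, cl = 1000, dt = dt)
      iso_cell <- set_cell_state(
        build_cell(model_id, r, m, caf = FALSE, iso = TRUE), base$state)
      tr <- pace(iso_cell, pacing_protocol(n_s1 = iso_beats, s1_cl = 1000),
                 dt = dt)
      counts <- vapply(seq(iso_beats - n_last + 1, iso_beats), function(b)
        tryCatch(detect_eads(tr, b), error = function(e) 0L), integer(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        mutation = m, region = r, ead_count = max(counts),
        has_ead = max(counts) >= 1)
    }
  }
  dplyr::bind_rows(rows)
}

validate_config <- function(config) {
  if (is.null(config$experiment))
    stop("config field 'experiment' is required")
  if (!config$experiment %in% known_experiments)
    stop("config field 'experiment': unknown experiment '",
         config$experiment, "'")
  p <- config$params
  if (!is.null(p$mutation)) {
    known <- c("WT", "D322H", kcna5_variants()$mutation)
    bad <- setdiff(toupper(unlist(p$mutation)), known)
    if (length(bad))
      stop("config field 'params.mutation': unknown mutation label '",
           paste(bad, collapse = "', '"), "'")
  }
  if (!is.null(p$region) &&
      !all(unlist(p$region) %in% c("RA", "CT", "PM")))
    stop("config field 'params.region': unknown region")
  invisible(config)
}

#' Run a configured experiment with provenance capture
#'
#' Dispatches one of the bundled experiments.  The output directory receives
#' `config.json` (an echo of the configuration), `metrics.json`, a `traces/`
#' subdirectory with CSV trace tables where applicable, and `log.txt`.
#' Identical configurations give bit-identical metrics; partial sub-task
#' failures are recorded in the metrics, not raised.
#'
#' @param config A list (or path to a JSON file) with fields `experiment`,
#'   `params` (experiment-specific), `seed`, `output_dir` (optional; no
#'   files written when absent).
#' @return The metrics list, invisibly carrying the `config` as attribute.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  config$seed <- config$seed %||% 1L
  config$params <- config$params %||% list()
  validate_config(config)
  p <- config$params
  seed <- as.integer(config$seed)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  note("experiment %s, seed %d", config$experiment, seed)

  traces <- list()
  metrics <- tryCatch(switch(
    config$experiment,
    "clamp-fit" = {
      fit <- fit_channel_variant(p$mutation %||% "WT",
                                 noise_sd = p$noise_sd %||% 0, seed = seed)
      list(activation = as.list(tidy(fit$act)$estimate),
           inactivation = as.list(tidy(fit$inact)$estimate),
           g_max = fit$g)
    },
    "table1-roundtrip" = {
      tab <- table1_roundtrip(noise_sd = p$noise_sd %||% 0, seed = seed)
      list(deltas = tab, max_abs_error = max(tab$max_abs_error))
    },
    "cell-sim" = {
      cell <- build_cell(p$model_id %||% "courtemanche_newIKur",
                         p$region %||% "RA", p$mutation %||% "WT",
                         isTRUE(p$caf), isTRUE(p$iso))
      tr <- pace(cell, pacing_protocol(n_s1 = p$n_beats %||% 10,
                                       s1_cl = p$cl %||% 1000))
      traces$ap <- tr
      as.list(measure_ap(tr))
    },
    "restitution" = {
      cell <- build_cell(p$model_id %||% "courtemanche_newIKur",
                         p$region %||% "RA", p$mutation %||% "WT",
                         isTRUE(p$caf), isTRUE(p$iso))
      rc <- restitution(cell, p$s2_grid %||% seq(300, 900, 100),
                        n_s1 = p$n_s1 %||% 20)
      list(restitution = rc)
    },
    "ead-scan" = {
      tab <- ead_scan(p$model_id %||% "grandi",
                      p$mutations %||% c("WT", "Y155C", "D469E", "P488S"),
                      p$regions %||% c("RA", "CT", "PM"),
                      pre_beats = p$pre_beats %||% 50,
                      iso_beats = p$iso_beats %||% 10)
      list(ead_matrix = tab)
    },
    "strand-cv" = {
      cell <- build_cell(p$model_id %||% "courtemanche_newIKur",
                         p$region %||% "RA", p$mutation %||% "WT")
      cfg <- cable_config(cell, n_nodes = p$n_nodes %||% 200,
                          dx = p$dx %||% 0.25)
      cal <- calibrate_diffusion(cfg, target_cv = p$target_cv %||% 1.3,
                                 tolerance = p$tolerance %||% 0.01)
      list(D = cal$D, cv = cal$cv, iterations = cal$iterations)
    },
    "vw-scan" = {
      cfg <- ctpm_strand(p$model_id %||% "grandi", p$mutation %||% "WT",
                         isTRUE(p$caf), isTRUE(p$iso),
                         n_nodes = p$n_nodes %||% 200,
                         D = p$D %||% 0.1)
      prep <- s1s2_prepare(cfg, n_s1 = p$n_s1 %||% 7,
                           s1_cl = p$s1_cl %||% 500)
      vw <- vulnerability_window(prep, scan = p$scan %||% c(150, 800))
      as.list(vw)
    },
    "san-pattern" = {
      tab <- san_conduction_pattern(p$model_id %||% "grandi",
                                    p$mutation %||% "WT",
                                    isTRUE(p$caf), p$iso %||% "uniform",
                                    n_beats = p$n_beats %||% 6)
      list(pattern = tab)
    },
    "reentry-2d" = {
      cell <- build_cell(p$model_id %||% "courtemanche", p$region %||% "RA",
                         p$mutation %||% "WT", isTRUE(p$caf), FALSE)
      lib <- build_phase_library(cell, cycle_length = p$cl %||% 1000,
                                 n_snapshots = p$n_snapshots %||% 64,
                                 n_beats = p$lib_beats %||% 30)
      sheet <- sheet_config(cell, nx = p$nx %||% 100, ny = p$ny %||% 100,
                            d_scale = p$d_scale %||% 1)
      init <- init_sheet_phase_map(sheet, lib)
      rm <- run_reentry(sheet, init, duration = p$duration %||% 2000)
      list(df_hz = rm$df_hz, sustained = attr(rm, "sustained"),
           lifetime = attr(rm, "lifetime"))
    }
  ), error = function(e) list(error = conditionMessage(e)))
  if (!is.null(metrics$error)) note("FAILED: %s", metrics$error)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(config, file.path(config$output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(metrics, file.path(config$output_dir,
                                            "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    if (length(traces)) {
      dir.create(file.path(config$output_dir, "traces"),
                 showWarnings = FALSE)
      for (nm in names(traces))
        utils::write.csv(traces[[nm]],
                         file.path(config$output_dir, "traces",
                                   paste0(nm, ".csv")), row.names = FALSE)
    }
    writeLines(log, file.path(config$output_dir, "log.txt"))
  }
  structure(metrics, config = config)
}

#' Summarise experiment bundles into a comparison table
#'
#' Collects `cell-sim`-style AP metrics from a list of result bundles into a
#' WT-vs-variant comparison table: absolute values per condition plus
#' differences against the WT row where one is present.  Missing entries
#' stay `NA`, never silently zero.
#'
#' @param bundles A list of [run_experiment()] results (or paths to
#'   `metrics.json` files with their `config.json` beside them).
#' @return A tibble with one row per condition.
#' @export
report_summary <- function(bundles) {
  rows <- lapply(bundles, function(b) {
    if (is.character(b)) {
      cfg <- jsonlite::read_json(file.path(dirname(b), "config.json"),
                                 simplifyVector = TRUE)
      b <- structure(jsonlite::read_json(b, simplifyVector = TRUE),
                     config = cfg)
    }
    cfg <- attr(b, "config")
    p <- cfg$params %||% list()
    tibble::tibble(
      experiment = cfg$experiment %||% NA_character_,
      model_id = p$model_id %||% NA_character_,
      region = p$region %||% "RA",
      mutation = toupper(p$mutation %||% "WT"),
      caf = isTRUE(p$caf), iso = isTRUE(p$iso),
      apd30 = b$apd30 %||% NA_real_,
      apd90 = b$apd90 %||% NA_real_,
      plateau_v = b$plateau_v %||% NA_real_,
      ead_count = b$ead_count %||% NA_real_,
      vw_width = b$width %||% NA_real_,
      cv = b$cv %||% NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  wt <- out[out$mutation == "WT" & !out$caf & !out$iso, ]
  if (nrow(wt) == 1) {
    out$d_apd30 <- out$apd30 - wt$apd30
    out$d_apd90 <- out$apd90 - wt$apd90
    out$d_plateau_v <- out$plateau_v - wt$plateau_v
  } else {
    out$d_apd30 <- out$d_apd90 <- out$d_plateau_v <- NA_real_
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
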