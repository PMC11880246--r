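# End-to-end orchestration: simulate (or load) traces at several holding
# potentials, analyze each, fit the I-V line, and invert the GHK equation
# for a permeability ratio. Configurable from YAML, reported as JSON.
# Units package-wide: mV, pA, pS, mM, ms, K.

#' Default simulation voltage protocol
#'
#' Five holding potentials bracketing the reversal potential and spanning
#' 190 mV, chosen so the smallest unitary current stays well clear of the
#' filtered noise floor at typical conductances.
#'
#' @param e_rev_mV reversal potential to bracket, mV.
#' @return numeric vector of 5 voltages, mV.
#' @export
default_voltages <- function(e_rev_mV) {
  e_rev_mV + c(-110, -80, -50, 50, 80)
}

#' Read and validate a pipeline configuration
#'
#' @param config a YAML file path or a named list with the same structure
#'   (see the packaged example:
#'   `system.file("extdata", "example_config.yaml", package = "bilayerlab")`).
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  cfg$mode <- cfg$mode %||% "simulate"
  need(cfg$mode %in% c("simulate", "load"), "mode must be simulate or load")
  if (identical(cfg$mode, "simulate")) {
    need(!is.null(cfg$seed), "simulate mode requires a seed")
    need(!is.null(cfg$channel$conductance_pS),
         "channel$conductance_pS is required")
    dur <- cfg$duration_s %||% 60
    need(is.numeric(dur) && dur > 0, "duration_s must be > 0")
    cfg$duration_s <- dur
  } else if (identical(cfg$mode, "load")) {
    files <- unlist(cfg$trace_files)
    need(length(files) > 0, "load mode requires trace_files")
    if (length(files)) {
      missing_files <- files[!file.exists(files)]
      need(length(missing_files) == 0,
           paste("missing trace files:",
                 paste(missing_files, collapse = ", ")))
    }
  }
  cfg$analysis <- modifyList(list(bin_width_pA = 0.05, min_open_ms = 1.5,
                                  weighted_iv = FALSE),
                             cfg$analysis %||% list())
  need(cfg$analysis$bin_width_pA > 0, "analysis$bin_width_pA must be > 0")
  need(cfg$analysis$min_open_ms >= 0, "analysis$min_open_ms must be >= 0")

  if (!is.null(cfg$bath)) {
    need(!is.null(cfg$bath$cis) && !is.null(cfg$bath$trans),
         "bath needs cis and trans salt lists")
  }
  if (length(problems))
    abort_bl(paste0("invalid pipeline config:\n  - ",
                    paste(problems, collapse = "\n  - ")),
             "bl_validation_error")
  structure(cfg, class = c("pipeline_config", class(cfg)))
}

.build_bath <- function(cfg) {
  if (is.null(cfg$bath)) return(NULL)
  bath_from_salts(unlist(cfg$bath$cis), unlist(cfg$bath$trans),
                  permeabilities = unlist(cfg$bath$permeabilities),
                  temperature_K = cfg$temperature_K %||% 298.15,
                  rt_over_f_mV = cfg$rt_over_f_mV)
}

.resolve_e_rev <- function(cfg, bath) {
  e <- cfg$channel$e_rev_mV
  if (!is.null(e)) return(e)
  if (is.null(bath))
    abort_bl("channel$e_rev_mV or a bath recipe is required",
             "bl_validation_error")
  ions <- names(bath$species)
  z <- vapply(bath$species, `[[`, 0L, "valence")
  if (any(z == 2L)) ghk_reversal_extended(bath)
  else ghk_reversal_monovalent(bath)
}

#' Run the full analysis pipeline
#'
#' In simulate mode: renders seeded traces at each holding potential with
#' the configured channel model, then analyzes each trace (all-point
#' histogram, Gaussian amplitude fit, idealization with the dead-time
#' rule, open probability), fits the I-V line, and — when a bath recipe
#' with permeabilities is configured — inverts the GHK equation at the
#' fitted reversal potential. In load mode the traces are read from TSV
#' instead. All randomness derives from the single master seed. When
#' `out_dir` is set, traces (simulate mode), event CSVs and the report
#' JSON are written there.
#'
#' @param config a `pipeline_config`, YAML path, or list.
#' @param out_dir optional output directory for artifacts.
#' @return a `pipeline_report` list: per-voltage amplitude and Po (NPo
#'   when `n_channels > 1`), the I-V fit, any permeability inversion, and
#'   provenance (seeds, config hash, package version).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  bath <- .build_bath(cfg)
  n_channels <- cfg$channel$n_channels %||% 1

  if (identical(cfg$mode, "simulate")) {
    e_rev <- .resolve_e_rev(cfg, bath)
    model <- channel_model(
      conductance_pS = cfg$channel$conductance_pS,
      e_rev_mV = e_rev,
      k_open_per_s = cfg$channel$k_open_per_s %||% 15,
      k_close_per_s = cfg$channel$k_close_per_s %||% 35,
      n_channels = n_channels,
      noise_sd_pA = cfg$channel$noise_sd_pA %||% 0.8,
      filter_cutoff_Hz = cfg$channel$filter_cutoff_Hz %||% 1000,
      sampling_rate_Hz = cfg$channel$sampling_rate_Hz %||% 10000)
    voltages <- unlist(cfg$voltages_mV) %||% default_voltages(e_rev)
    seeds <- derive_seeds(cfg$seed, length(voltages))
    traces <- Map(function(v, s)
      simulate_trace(model, cfg$duration_s * 1000, v, s),
      voltages, seeds)
  } else {
    traces <- lapply(unlist(cfg$trace_files), read_trace_tsv)
    voltages <- vapply(traces, `[[`, 0, "holding_potential_mV")
    seeds <- NULL
  }

  bath_label <- if (!is.null(cfg$bath))
    paste0("cis ", paste(names(cfg$bath$cis), unlist(cfg$bath$cis),
                         collapse = "+"),
           " : trans ", paste(names(cfg$bath$trans), unlist(cfg$bath$trans),
                              collapse = "+"))
  analyses <- lapply(traces, analyze_trace,
                     bin_width_pA = cfg$analysis$bin_width_pA,
                     min_open_ms = cfg$analysis$min_open_ms,
                     bath_label = bath_label)
  iv <- build_iv(analyses)
  ivfit <- fit_iv(iv, weighted = cfg$analysis$weighted_iv)

  perm <- NULL
  if (!is.null(cfg$ghk$invert) && !is.null(bath)) {
    perm <- switch(cfg$ghk$invert,
      monovalent = invert_monovalent_ratio(
        ivfit$e_rev_mV, bath,
        reference_cation = cfg$ghk$reference_cation,
        target_anion = cfg$ghk$target_anion),
      divalent = invert_divalent_ratio(
        ivfit$e_rev_mV, bath,
        include_anions = isTRUE(cfg$ghk$include_anions),
        reference = cfg$ghk$reference),
      abort_bl("ghk$invert must be monovalent or divalent",
               "bl_validation_error"))
  }

  po_label <- if (n_channels > 1) "npo" else "po"
  per_voltage <- Map(function(v, a) {
    out <- list(holding_mV = v,
                unitary_amplitude_pA = a$fit$unitary_amplitude_pA,
                amplitude_se_pA = a$fit$amplitude_se_pA,
                baseline_pA = a$baseline_pA,
                n_open_events = sum(a$events$events$state == "open"))
    out[[po_label]] <- a$po
    out
  }, voltages, analyses)

  report <- list(
    package = "bilayerlab",
    version = as.character(utils::packageVersion("bilayerlab")),
    mode = cfg$mode,
    bath = bath_label,
    per_voltage = unname(per_voltage),
    iv_fit = list(conductance_pS = ivfit$conductance_pS,
                  conductance_se_pS = ivfit$conductance_se_pS,
                  e_rev_mV = ivfit$e_rev_mV,
                  e_rev_se_mV = ivfit$e_rev_se_mV,
                  n_points = ivfit$n_points),
    permeability = if (!is.null(perm))
      list(numerator_species = perm$numerator_species,
           denominator_species = perm$denominator_species,
           ratio = perm$ratio, e_rev_mV = perm$e_rev_mV,
           rt_over_f_mV = perm$rt_over_f_mV, method = perm$method),
    provenance = list(master_seed = cfg$seed,
                      per_voltage_seeds = seeds,
                      config_hash = .config_hash(cfg)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(traces)) {
      tag <- sprintf("V%+04.0fmV", voltages[k])
      if (identical(cfg$mode, "simulate"))
        write_trace_tsv(traces[[k]],
                        file.path(out_dir, paste0("trace_", tag, ".tsv")))
      write_events_csv(analyses[[k]]$events,
                       file.path(out_dir, paste0("events_", tag, ".csv")))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(c(report, list(analyses = analyses, iv = iv, ivfit = ivfit)),
            class = "pipeline_report")
}

# md5 of the canonicalized config, for provenance
.config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (%s mode, %d voltages)\n", x$mode,
              length(x$per_voltage)))
  for (pv in x$per_voltage)
    cat(sprintf("  V = %+6.1f mV: amplitude %+.3f pA, %s = %.3f\n",
                pv$holding_mV, pv$unitary_amplitude_pA,
                if (!is.null(pv$npo)) "NPo" else "Po",
                pv$npo %||% pv$po))
  cat(sprintf("  g = %.2f +/- %.2f pS, E_rev = %.2f +/- %.2f mV\n",
              x$iv_fit$conductance_pS, x$iv_fit$conductance_se_pS,
              x$iv_fit$e_rev_mV, x$iv_fit$e_rev_se_mV))
  if (!is.null(x$permeability))
    cat(sprintf("  P_%s/P_%s = %.3f at E_rev = %.2f mV\n",
                x$permeability$numerator_species,
                x$permeability$denominator_species,
                x$permeability$ratio, x$permeability$e_rev_mV))
  invisible(x)
}
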