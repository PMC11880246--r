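# Seeded two-state Markov gating simulator and trace renderer.
# Emulates bilayer acquisition: exponential dwell times, ohmic unitary
# current, additive Gaussian noise, causal low-pass filter, point sampling.

#' Ground-truth model of a simulated channel
#'
#' @param conductance_pS unitary slope conductance, pS.
#' @param e_rev_mV reversal potential, mV (give directly or compute from a
#'   bath with [ghk_reversal_monovalent()] / [nernst_potential()]).
#' @param k_open_per_s closed-to-open rate, 1/s.
#' @param k_close_per_s open-to-closed rate, 1/s.
#' @param n_channels number of independent channels in the membrane.
#' @param noise_sd_pA SD of additive Gaussian noise, applied before
#'   filtering, pA.
#' @param filter_cutoff_Hz low-pass corner frequency (4-pole Butterworth);
#'   `NULL` disables filtering.
#' @param filter_order filter order; default 4.
#' @param sampling_rate_Hz acquisition rate, Hz.
#' @return an object of class `channel_model`.
#' @export
channel_model <- function(conductance_pS, e_rev_mV,
                          k_open_per_s = 15, k_close_per_s = 35,
                          n_channels = 1L, noise_sd_pA = 0.8,
                          filter_cutoff_Hz = 1000, filter_order = 4,
                          sampling_rate_Hz = 10000) {
  if (conductance_pS <= 0)
    abort_bl("conductance_pS must be > 0", "bl_domain_error")
  if (k_open_per_s <= 0 || k_close_per_s <= 0)
    abort_bl("gating rates must be > 0", "bl_domain_error")
  if (n_channels < 1)
    abort_bl("n_channels must be >= 1", "bl_domain_error")
  if (noise_sd_pA < 0)
    abort_bl("noise_sd_pA must be >= 0", "bl_domain_error")
  if (!is.null(filter_cutoff_Hz) &&
      sampling_rate_Hz <= 2 * filter_cutoff_Hz)
    abort_bl("sampling_rate_Hz must exceed 2 x filter_cutoff_Hz",
             "bl_domain_error")
  structure(list(conductance_pS = conductance_pS, e_rev_mV = e_rev_mV,
                 k_open_per_s = k_open_per_s, k_close_per_s = k_close_per_s,
                 n_channels = as.integer(n_channels),
                 noise_sd_pA = noise_sd_pA,
                 filter_cutoff_Hz = filter_cutoff_Hz,
                 filter_order = filter_order,
                 sampling_rate_Hz = sampling_rate_Hz),
            class = "channel_model")
}

#' Ohmic unitary current
#'
#' i = g (V - E_rev) / 1000, the single-channel current in pA for a
#' conductance in pS and potentials in mV.
#'
#' @param conductance_pS unitary conductance, pS (> 0).
#' @param holding_mV holding potential, mV.
#' @param e_rev_mV reversal potential, mV.
#' @return current in pA, signed (negative = inward by convention).
#' @examples
#' unitary_current(59.55, -50, 29.90)  # about -4.76 pA
#' @export
unitary_current <- function(conductance_pS, holding_mV, e_rev_mV) {
  if (conductance_pS <= 0)
    abort_bl("conductance_pS must be > 0", "bl_domain_error")
  conductance_pS * (holding_mV - e_rev_mV) / 1000
}

# one channel's alternating dwell sequence covering duration_ms
.simulate_one_channel <- function(k_open, k_close, duration_ms, p_open) {
  state <- runif(1) < p_open          # stationary start
  t <- 0
  states <- integer(0); dwells <- numeric(0)
  while (t < duration_ms) {
    rate <- if (state) k_close else k_open
    d <- rexp(1, rate) * 1000         # ms
    d <- min(d, duration_ms - t)      # truncate final dwell
    states <- c(states, as.integer(state))
    dwells <- c(dwells, d)
    t <- t + d
    state <- !state
  }
  list(states = states, dwells = dwells)
}

#' Simulate two-state Markov gating
#'
#' Draws a continuous-time alternating open/closed path with exponential
#' dwell times (rates `k_open_per_s`, `k_close_per_s`), starting from the
#' stationary distribution. For `n_channels > 1` independent channels are
#' simulated and merged; the path then records the instantaneous open
#' count. The final dwell is truncated at `duration_ms`.
#'
#' @param model a [channel_model()].
#' @param duration_ms path length, ms.
#' @param seed integer seed; required for reproducibility.
#' @return an object of class `gating_path`: a data.frame with columns
#'   `state` (open count), `dwell_ms`, plus attributes `total_duration_ms`
#'   and `model`.
#' @export
simulate_gating <- function(model, duration_ms, seed) {
  stopifnot(inherits(model, "channel_model"))
  if (duration_ms <= 0)
    abort_bl("duration_ms must be > 0", "bl_domain_error")
  if (missing(seed) || is.null(seed))
    abort_bl("an explicit seed is required", "bl_usage_error")
  set.seed(seed)
  p_open <- model$k_open_per_s / (model$k_open_per_s + model$k_close_per_s)
  chans <- replicate(model$n_channels,
                     .simulate_one_channel(model$k_open_per_s,
                                           model$k_close_per_s,
                                           duration_ms, p_open),
                     simplify = FALSE)
  if (model$n_channels == 1L) {
    st <- chans[[1]]$states
    dw <- chans[[1]]$dwells
  } else {
    # merge: open count is the sum of channel states between transitions
    bounds <- sort(unique(c(0, unlist(lapply(chans, function(ch)
      cumsum(ch$dwells))))))
    bounds[length(bounds)] <- duration_ms
    mids <- (head(bounds, -1) + tail(bounds, -1)) / 2
    count <- Reduce(`+`, lapply(chans, function(ch) {
      ends <- cumsum(ch$dwells)
      ch$states[findInterval(mids, c(0, head(ends, -1)))]
    }))
    dw <- diff(bounds)
    st <- count
    # collapse zero-length intervals and equal neighbours
    keep <- dw > 0
    st <- st[keep]; dw <- dw[keep]
    if (length(st) > 1) {
      r <- rle(st)
      dw <- as.numeric(rowsum(dw, rep(seq_along(r$lengths), r$lengths)))
      st <- r$values
    }
  }
  path <- data.frame(state = st, dwell_ms = dw)
  structure(path, total_duration_ms = duration_ms, model = model,
            seed = seed, class = c("gating_path", "data.frame"))
}

#' Render a gating path into a sampled current trace
#'
#' The ideal piecewise-constant current (open count times unitary current)
#' is point-sampled at the model's sampling rate, Gaussian noise is added,
#' and the sum is passed through a causal low-pass Butterworth filter —
#' the same order of operations as an amplifier/filter/digitizer chain.
#' Events shorter than the sampling interval can vanish, as in real
#' acquisition.
#'
#' @param path a `gating_path`.
#' @param model a [channel_model()] (defaults to the path's model).
#' @param holding_mV holding potential, mV.
#' @param seed integer seed for the noise generator.
#' @return an object of class `sc_trace`: list with `current_pA`,
#'   `sampling_rate_Hz`, `holding_potential_mV` and `metadata`.
#' @export
render_trace <- function(path, model = attr(path, "model"), holding_mV,
                         seed) {
  stopifnot(inherits(path, "gating_path"), inherits(model, "channel_model"))
  if (missing(seed) || is.null(seed))
    abort_bl("an explicit seed is required", "bl_usage_error")
  fs <- model$sampling_rate_Hz
  total_ms <- attr(path, "total_duration_ms")
  n <- round(total_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  ends <- cumsum(path$dwell_ms)
  idx <- findInterval(t_ms, c(0, head(ends, -1)))
  i_unit <- unitary_current(model$conductance_pS, holding_mV, model$e_rev_mV)
  ideal <- path$state[idx] * i_unit
  set.seed(seed)
  x <- ideal + if (model$noise_sd_pA > 0)
    rnorm(n, 0, model$noise_sd_pA) else 0
  if (!is.null(model$filter_cutoff_Hz)) {
    bf <- signal::butter(model$filter_order,
                         model$filter_cutoff_Hz / (fs / 2), type = "low")
    x <- as.numeric(signal::filter(bf, x))
  }
  new_trace(x, fs, holding_mV,
            metadata = list(model = unclass(model), seed = seed,
                            ideal_open_fraction =
                              sum(path$dwell_ms[path$state > 0]) / total_ms))
}

#' Construct a trace object
#'
#' @param current_pA numeric vector of current samples, pA.
#' @param sampling_rate_Hz sampling rate, Hz.
#' @param holding_mV holding potential, mV.
#' @param metadata free-form list (bath description, seed, model ...).
#' @return an object of class `sc_trace`.
#' @export
new_trace <- function(current_pA, sampling_rate_Hz, holding_mV,
                      metadata = list()) {
  if (!length(current_pA) || !all(is.finite(current_pA)))
    abort_bl("current_pA must be non-empty and finite", "bl_input_error")
  structure(list(current_pA = as.numeric(current_pA),
                 sampling_rate_Hz = sampling_rate_Hz,
                 holding_potential_mV = holding_mV,
                 metadata = metadata),
            class = "sc_trace")
}

#' Duration of a trace in milliseconds
#' @param trace an `sc_trace`.
#' @export
trace_duration_ms <- function(trace) {
  length(trace$current_pA) / trace$sampling_rate_Hz * 1000
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf("Single-channel trace: %d samples at %g kHz (%.1f s), V = %g mV\n",
              length(x$current_pA), x$sampling_rate_Hz / 1000,
              trace_duration_ms(x) / 1000, x$holding_potential_mV))
  invisible(x)
}

#' Simulate a complete trace in one call
#'
#' Convenience wrapper: [simulate_gating()] then [render_trace()], with
#' sub-seeds for gating and noise derived deterministically from one seed.
#'
#' @inheritParams simulate_gating
#' @param holding_mV holding potential, mV.
#' @return an `sc_trace`.
#' @export
simulate_trace <- function(model, duration_ms, holding_mV, seed) {
  seeds <- derive_seeds(seed, 2)
  path <- simulate_gating(model, duration_ms, seeds[1])
  render_trace(path, model, holding_mV, seeds[2])
}

#' Derive independent sub-seeds from a master seed
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in \[1, 2^31 - 2\].
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Write a trace as TSV with a JSON sidecar
#'
#' The TSV has a header row and two columns, `time_s` and `current_pA`.
#' A sidecar `<path>.json` records sampling rate, holding potential and
#' metadata, so the trace round-trips through [read_trace_tsv()].
#'
#' @param trace an `sc_trace`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "sc_trace"))
  n <- length(trace$current_pA)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$sampling_rate_Hz,
                   current_pA = trace$current_pA)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(format_version = "1.0",
                  sampling_rate_Hz = trace$sampling_rate_Hz,
                  holding_potential_mV = trace$holding_potential_mV,
                  metadata = trace$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace written by [write_trace_tsv()]
#'
#' @param path TSV path; the sidecar `<path>.json` is read when present,
#'   otherwise the sampling rate is inferred from the time column and the
#'   holding potential must be supplied.
#' @param holding_mV fallback holding potential when no sidecar exists.
#' @return an `sc_trace`.
#' @export
read_trace_tsv <- function(path, holding_mV = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "current_pA") %in% names(df)))
    abort_bl("trace TSV must have columns time_s and current_pA",
             "bl_input_error")
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    new_trace(df$current_pA, meta$sampling_rate_Hz,
              meta$holding_potential_mV,
              metadata = meta$metadata %||% list())
  } else {
    if (nrow(df) < 2) abort_bl("trace too short", "bl_input_error")
    fs <- 1 / median(diff(df$time_s))
    if (is.null(holding_mV))
      abort_bl("no sidecar: supply holding_mV", "bl_input_error")
    new_trace(df$current_pA, fs, holding_mV)
  }
}
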