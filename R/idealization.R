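# Half-amplitude threshold idealization with a fixed dead time, and the
# open-probability estimator Po = t_open / T.

#' Estimate the closed-level baseline of a trace
#'
#' Locates the dominant peak of the all-point histogram and refines it by
#' an iterated symmetric mean (mean-shift) inside a window scaled to the
#' peak's half-width at half-maximum, which converges to the center of
#' the local peak and is root-n consistent for a Gaussian closed level
#' while ignoring the open-level peak. Falls back to the median when no
#' histogram peak can be identified.
#'
#' @param trace an `sc_trace` or numeric vector of samples, pA.
#' @param bin_width_pA histogram bin width, pA.
#' @param window_pA half-width of the refinement window; default: the
#'   dominant peak's half-width at half-maximum (at least 2 bins).
#' @return baseline current, pA.
#' @export
estimate_baseline <- function(trace, bin_width_pA = 0.05,
                              window_pA = NULL) {
  x <- if (inherits(trace, "sc_trace")) trace$current_pA else as.numeric(trace)
  if (!length(x)) abort_bl("empty trace", "bl_input_error")
  if (diff(range(x)) < bin_width_pA) return(mean(x))
  h <- all_point_histogram(x, bin_width_pA)
  centers <- (head(h$bin_edges_pA, -1) + tail(h$bin_edges_pA, -1)) / 2
  k <- which.max(h$counts)
  if (!length(k) || h$counts[k] == 0) return(median(x))
  if (is.null(window_pA)) {
    # half-width at half-maximum of the dominant peak
    half <- h$counts[k] / 2
    right <- which(h$counts[k:length(h$counts)] < half)
    left <- which(rev(h$counts[1:k]) < half)
    hw_r <- if (length(right)) right[1] - 1 else length(h$counts) - k
    hw_l <- if (length(left)) left[1] - 1 else k - 1
    # 2 x HWHM (~2.4 sigma for a Gaussian peak): wide enough that the
    # windowed mean is nearly as efficient as the full mean, narrow
    # enough to exclude a separated open-level peak
    window_pA <- max(2, hw_l + hw_r) * bin_width_pA
  }
  center <- centers[k]
  for (i in 1:50) {
    inside <- x[abs(x - center) <= window_pA]
    if (!length(inside)) return(median(x))
    new_center <- mean(inside)
    if (abs(new_center - center) < 1e-9) break
    center <- new_center
  }
  center
}

#' Idealize a trace into open/closed events
#'
#' Classifies each sample by the half-amplitude criterion (threshold at
#' baseline + 0.5 x unitary amplitude, on the side of the amplitude's
#' sign), turns contiguous runs into events, and re-merges open events
#' shorter than the dead time `min_open_ms` into the surrounding closed
#' level, so that sub-dead-time openings do not contribute to the open
#' time. The events tile the trace without gaps or overlap and alternate
#' in state. The baseline is re-estimated from the trace, making the
#' idealization invariant to a constant offset.
#'
#' @param trace an `sc_trace`.
#' @param unitary_amplitude_pA signed open-channel amplitude relative to
#'   baseline, pA (e.g. from [fit_amplitude_gaussians()]).
#' @param min_open_ms dead time: open events shorter than this are
#'   ignored. Default 1.5 ms.
#' @param min_closed_ms optional symmetric dead time for closed gaps;
#'   default 0 (off).
#' @param baseline_pA optional fixed baseline; default estimated with
#'   [estimate_baseline()].
#' @return an object of class `event_table`: list with `events` (a
#'   data.frame `state`, `start_ms`, `duration_ms`, `mean_current_pA`),
#'   `trace_duration_ms` and the parameters used.
#' @export
idealize <- function(trace, unitary_amplitude_pA, min_open_ms = 1.5,
                     min_closed_ms = 0, baseline_pA = NULL) {
  stopifnot(inherits(trace, "sc_trace"))
  x <- trace$current_pA
  if (!length(x)) abort_bl("empty trace", "bl_input_error")
  if (abs(unitary_amplitude_pA) <= 0)
    abort_bl("unitary_amplitude_pA must be non-zero", "bl_domain_error")
  if (min_open_ms < 0)
    abort_bl("min_open_ms must be >= 0", "bl_domain_error")
  fs <- trace$sampling_rate_Hz
  base <- baseline_pA %||% estimate_baseline(trace)
  thr <- base + 0.5 * unitary_amplitude_pA
  open <- if (unitary_amplitude_pA > 0) x >= thr else x <= thr
  # sanity: the trace should actually excurse toward the stated amplitude
  excur <- if (unitary_amplitude_pA > 0) max(x) - base else base - min(x)
  if (!any(open) && excur < 0.5 * abs(unitary_amplitude_pA))
    warn_bl("no excursions consistent with the stated amplitude sign; returning an all-closed table",
            "bl_amplitude_sign_warning")

  r <- rle(open)
  states <- r$values
  lens <- r$lengths
  dur_ms <- lens / fs * 1000
  # dead-time rule: sub-dead-time open events rejoin the closed level
  states[states & dur_ms < min_open_ms] <- FALSE
  if (min_closed_ms > 0)
    states[!states & dur_ms < min_closed_ms &
             seq_along(states) > 1 &
             seq_along(states) < length(states)] <- TRUE
  # merge adjacent runs that now share a state
  grp <- cumsum(c(TRUE, states[-1] != states[-length(states)]))
  lens2 <- as.numeric(rowsum(lens, grp))
  states2 <- states[!duplicated(grp)]
  ends <- cumsum(lens2)
  starts <- c(0, head(ends, -1))
  mean_i <- vapply(seq_along(lens2), function(k)
    mean(x[(starts[k] + 1):ends[k]]), 0)
  events <- data.frame(state = ifelse(states2, "open", "closed"),
                       start_ms = starts / fs * 1000,
                       duration_ms = lens2 / fs * 1000,
                       mean_current_pA = mean_i,
                       stringsAsFactors = FALSE)
  structure(list(events = events,
                 trace_duration_ms = length(x) / fs * 1000,
                 threshold_pA = thr, baseline_pA = base,
                 min_open_ms = min_open_ms, min_closed_ms = min_closed_ms,
                 unitary_amplitude_pA = unitary_amplitude_pA),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  n_open <- sum(x$events$state == "open")
  cat(sprintf("Event table: %d events (%d open) over %.1f ms, Po = %.3f\n",
              nrow(x$events), n_open, x$trace_duration_ms,
              open_probability(x)))
  invisible(x)
}

#' Open probability from an event table
#'
#' Po = sum of open durations / total trace duration. For recordings with
#' more than one channel the same quantity is conventionally reported as
#' NPo; the caller labels it.
#'
#' @param events an `event_table`.
#' @return fraction in \[0, 1\].
#' @export
open_probability <- function(events) {
  stopifnot(inherits(events, "event_table"))
  if (events$trace_duration_ms <= 0)
    abort_bl("trace_duration_ms must be > 0", "bl_domain_error")
  sum(events$events$duration_ms[events$events$state == "open"]) /
    events$trace_duration_ms
}

#' Write an event table as CSV
#'
#' Columns: state, start_ms, duration_ms, mean_current_pA.
#'
#' @param events an `event_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.csv(events$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
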