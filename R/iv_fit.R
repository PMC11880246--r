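# Unitary current vs holding potential: slope conductance and reversal
# potential from a straight-line (ohmic) fit.

#' Assemble an I-V dataset
#'
#' @param holding_mV numeric vector of holding potentials, mV.
#' @param current_pA unitary currents at those potentials, pA.
#' @param se_pA optional standard errors of the currents, pA.
#' @param n_events optional event counts behind each point.
#' @param bath optional bath description (character or `bath_pair`).
#' @return object of class `iv_dataset`: data.frame of points with a
#'   `bath` attribute.
#' @export
iv_dataset <- function(holding_mV, current_pA, se_pA = NULL,
                       n_events = NULL, bath = NULL) {
  if (length(holding_mV) != length(current_pA))
    abort_bl("holding_mV and current_pA must have equal length",
             "bl_input_error")
  if (length(unique(holding_mV)) < 2)
    abort_bl("need at least 2 distinct voltages", "bl_input_error")
  if (!all(is.finite(current_pA)))
    abort_bl("currents must be finite", "bl_input_error")
  df <- data.frame(holding_mV = holding_mV, current_pA = current_pA,
                   se_pA = se_pA %||% NA_real_,
                   n_events = n_events %||% NA_integer_)
  structure(df, bath = bath, class = c("iv_dataset", "data.frame"))
}

#' Build an I-V dataset from per-trace analyses
#'
#' Takes the per-trace results of [analyze_trace()] (a Gaussian amplitude
#' fit at a known holding potential each) and produces one I-V point per
#' voltage. Duplicate voltages are pooled by inverse-variance averaging
#' when standard errors are available, otherwise by the plain mean.
#'
#' @param analyses list of `trace_analysis` objects.
#' @return an `iv_dataset`.
#' @export
build_iv <- function(analyses) {
  if (!length(analyses))
    abort_bl("no analyses supplied", "bl_input_error")
  ok <- vapply(analyses, inherits, TRUE, "trace_analysis")
  if (!all(ok))
    abort_bl("build_iv expects trace_analysis objects", "bl_input_error")
  baths <- unique(vapply(analyses,
                         function(a) a$bath_label %||% "", ""))
  if (length(baths) > 1)
    abort_bl("analyses mix different bath descriptions", "bl_input_error")
  v <- vapply(analyses, `[[`, 0, "holding_mV")
  amp <- vapply(analyses, function(a) a$fit$unitary_amplitude_pA, 0)
  se <- vapply(analyses, function(a) a$fit$amplitude_se_pA %||% NA_real_, 0)
  pool <- lapply(split(seq_along(v), v), function(idx) {
    if (length(idx) == 1 || any(!is.finite(se[idx])) || any(se[idx] <= 0)) {
      c(i = mean(amp[idx]),
        se = if (length(idx) > 1) sd(amp[idx]) / sqrt(length(idx))
             else se[idx])
    } else {
      w <- 1 / se[idx]^2
      c(i = sum(w * amp[idx]) / sum(w), se = sqrt(1 / sum(w)))
    }
  })
  vv <- as.numeric(names(pool))
  m <- do.call(rbind, pool)
  iv_dataset(vv, m[, "i"], se_pA = m[, "se"],
             bath = baths[baths != ""][1] %||% NULL)
}

#' Fit a straight line to an I-V dataset
#'
#' Ordinary or inverse-variance weighted least squares of
#' i = a V + b. The slope conductance is 1000 a (pA/mV = nS, reported in
#' pS) and the reversal potential is the x-intercept -b/a, with its
#' standard error by the delta method.
#'
#' @param data an `iv_dataset` (or data.frame with `holding_mV`,
#'   `current_pA` and optionally `se_pA`).
#' @param weighted use 1/se^2 weights; requires all `se_pA` > 0.
#' @return object of class `iv_fit_result`: list with `conductance_pS`,
#'   `e_rev_mV`, `conductance_se_pS`, `e_rev_se_mV`, `residuals_pA` and
#'   the underlying `lm` fit.
#' @export
fit_iv <- function(data, weighted = FALSE) {
  df <- as.data.frame(data)
  if (length(unique(df$holding_mV)) < 2)
    abort_bl("need at least 2 distinct voltages", "bl_input_error")
  w <- NULL
  if (weighted) {
    if (any(!is.finite(df$se_pA)) || any(df$se_pA <= 0))
      abort_bl("weighted fit requires positive se_pA for every point",
               "bl_input_error")
    w <- 1 / df$se_pA^2
  }
  fit <- lm(current_pA ~ holding_mV, data = df, weights = w)
  a <- coef(fit)[["holding_mV"]]
  b <- coef(fit)[["(Intercept)"]]
  if (a == 0)
    abort_bl("zero slope: reversal potential undefined", "bl_no_solution")
  # collinear points fit exactly; lm warns that its summary is unreliable
  V <- suppressWarnings(vcov(fit))
  # with n = 2 the fit is exact and lm's vcov is NaN; report 0 SEs
  if (any(!is.finite(V))) V <- matrix(0, 2, 2,
                                      dimnames = dimnames(V))
  se_a <- sqrt(V["holding_mV", "holding_mV"])
  se_b <- sqrt(V["(Intercept)", "(Intercept)"])
  cov_ab <- V["(Intercept)", "holding_mV"]
  e_rev <- -b / a
  # delta method for -b/a
  e_rev_se <- sqrt((se_b / a)^2 + (b * se_a / a^2)^2 -
                     2 * (b / a^3) * cov_ab)
  structure(list(conductance_pS = 1000 * a,
                 conductance_se_pS = 1000 * se_a,
                 e_rev_mV = e_rev, e_rev_se_mV = e_rev_se,
                 residuals_pA = stats::resid(fit),
                 n_points = nrow(df), weighted = weighted, lm_fit = fit),
            class = "iv_fit_result")
}

#' @export
print.iv_fit_result <- function(x, ...) {
  cat(sprintf("I-V fit (%d points%s): g = %.2f +/- %.2f pS, E_rev = %.2f +/- %.2f mV\n",
              x$n_points, if (x$weighted) ", weighted" else "",
              x$conductance_pS, x$conductance_se_pS,
              x$e_rev_mV, x$e_rev_se_mV))
  invisible(x)
}

#' Analyze one trace: histogram fit, idealization, open probability
#'
#' The standard per-trace workflow: all-point histogram, two-Gaussian
#' amplitude fit, half-amplitude idealization with the dead-time rule,
#' and the open probability.
#'
#' @param trace an `sc_trace`.
#' @param bin_width_pA histogram bin width, pA.
#' @param min_open_ms dead time for idealization, ms.
#' @param bath_label optional bath description carried into [build_iv()].
#' @return object of class `trace_analysis`: list with `holding_mV`,
#'   `fit` (the `gaussian_pair_fit`), `events`, `po`, `baseline_pA`.
#' @export
analyze_trace <- function(trace, bin_width_pA = 0.05, min_open_ms = 1.5,
                          bath_label = NULL) {
  stopifnot(inherits(trace, "sc_trace"))
  base <- estimate_baseline(trace, bin_width_pA)
  h <- all_point_histogram(trace, bin_width_pA)
  fit <- fit_amplitude_gaussians(h, baseline_pA = base)
  ev <- idealize(trace, fit$unitary_amplitude_pA, min_open_ms,
                 baseline_pA = fit$closed$mean_pA)
  structure(list(holding_mV = trace$holding_potential_mV,
                 fit = fit, events = ev, po = open_probability(ev),
                 baseline_pA = base, histogram = h,
                 bath_label = bath_label),
            class = "trace_analysis")
}
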