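# All-point amplitude histograms and two-component Gaussian fits for the
# unitary current, the standard way conductance levels are read off a
# single-channel trace.

#' All-point current histogram
#'
#' Uniform binning of every sample in the trace; every sample falls in
#' exactly one bin, so the counts sum to the trace length.
#'
#' @param trace an `sc_trace` or numeric vector, pA.
#' @param bin_width_pA bin width, pA; default 0.05.
#' @return object of class `ap_histogram`: list with `bin_edges_pA`,
#'   `counts`, `bin_width_pA`, `n_samples`.
#' @export
all_point_histogram <- function(trace, bin_width_pA = 0.05) {
  x <- if (inherits(trace, "sc_trace")) trace$current_pA else as.numeric(trace)
  if (!length(x)) abort_bl("empty trace", "bl_input_error")
  if (bin_width_pA <= 0)
    abort_bl("bin_width_pA must be > 0", "bl_domain_error")
  lo <- floor(min(x) / bin_width_pA) * bin_width_pA
  hi <- ceiling(max(x) / bin_width_pA) * bin_width_pA
  if (hi <= lo) hi <- lo + bin_width_pA
  edges <- seq(lo, hi + bin_width_pA / 2, by = bin_width_pA)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(list(bin_edges_pA = edges, counts = counts,
                 bin_width_pA = bin_width_pA, n_samples = length(x)),
            class = "ap_histogram")
}

#' @export
print.ap_histogram <- function(x, ...) {
  cat(sprintf("All-point histogram: %d samples in %d bins of %g pA over [%g, %g] pA\n",
              x$n_samples, length(x$counts), x$bin_width_pA,
              min(x$bin_edges_pA), max(x$bin_edges_pA)))
  invisible(x)
}

.hist_centers <- function(h)
  (head(h$bin_edges_pA, -1) + tail(h$bin_edges_pA, -1)) / 2

# local maxima of the (lightly smoothed) counts, tallest first. A peak is
# accepted only if it is separated from every already-accepted peak by
# min_sep_pA AND by a genuine valley (intervening minimum below 80% of
# the peak's own height), which rejects shot-noise bumps on the shoulder
# of a single broad level.
.find_peaks <- function(centers, counts, min_sep_pA, smooth_bins = 5) {
  k <- min(smooth_bins, length(counts))
  if (k > 1) {
    kern <- rep(1 / k, k)
    sm <- as.numeric(stats::filter(counts, kern, sides = 2))
    sm[is.na(sm)] <- counts[is.na(sm)]
  } else sm <- counts
  n <- length(sm)
  if (n < 3) return(integer(0))
  is_max <- sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & counts > 0
  cand <- which(is_max)[order(sm[is_max], decreasing = TRUE)]
  # a real conductance level holds an appreciable share of the samples;
  # lone far-tail bins do not
  cand <- cand[sm[cand] >= 0.05 * max(sm[cand])]
  picked <- integer(0)
  for (i in cand) {
    sep_ok <- all(abs(centers[i] - centers[picked]) >= min_sep_pA)
    valley_ok <- all(vapply(picked, function(j) {
      between <- sm[seq(min(i, j), max(i, j))]
      min(between) < 0.8 * sm[i]
    }, TRUE))
    if (sep_ok && valley_ok) picked <- c(picked, i)
  }
  picked
}

#' Fit a two-component Gaussian to an all-point histogram
#'
#' Nonlinear least squares of the sum of two Gaussians to the bin counts
#' (the approach of standard acquisition software), initialized at the two
#' tallest local maxima separated by at least `min_sep_pA`. The component
#' nearer `baseline_pA` is labeled "closed"; the signed unitary amplitude
#' is mean(open) - mean(closed).
#'
#' @param hist an `ap_histogram`.
#' @param baseline_pA reference for labeling the closed component;
#'   default: center of the tallest bin.
#' @param min_sep_pA minimum peak separation for a non-degenerate fit,
#'   pA; default 0.5.
#' @return object of class `gaussian_pair_fit`: list with `closed` and
#'   `open` components (`mean_pA`, `sd_pA`, `weight`),
#'   `unitary_amplitude_pA`, `rss` and the fitted model.
#'   A unimodal histogram raises a condition of class
#'   `bl_degenerate_fit` carrying the single-component fit in its
#'   `single_fit` field.
#' @export
fit_amplitude_gaussians <- function(hist, baseline_pA = NULL,
                                    min_sep_pA = 0.5) {
  stopifnot(inherits(hist, "ap_histogram"))
  centers <- .hist_centers(hist)
  counts <- hist$counts
  bw <- hist$bin_width_pA
  baseline_pA <- baseline_pA %||% centers[which.max(counts)]
  peaks <- .find_peaks(centers, counts, min_sep_pA)
  if (length(peaks) < 2) {
    m0 <- sum(centers * counts) / sum(counts)
    s0 <- sqrt(max(sum((centers - m0)^2 * counts) / sum(counts), (bw / 2)^2))
    single <- list(mean_pA = m0, sd_pA = s0, weight = 1)
    stop(errorCondition(
      "histogram is unimodal: cannot resolve separate closed and open levels",
      single_fit = single,
      class = c("bl_degenerate_fit", "bilayerlab_error")))
  }
  p1 <- peaks[1]; p2 <- peaks[2]
  start <- c(a1 = max(counts[p1], 1), m1 = centers[p1], s1 = 4 * bw,
             a2 = max(counts[p2], 1), m2 = centers[p2], s2 = 4 * bw)
  two_gauss <- function(p, x)
    p[["a1"]] * exp(-(x - p[["m1"]])^2 / (2 * p[["s1"]]^2)) +
    p[["a2"]] * exp(-(x - p[["m2"]])^2 / (2 * p[["s2"]]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) two_gauss(p, centers) - counts,
      lower = c(0, min(centers), bw / 4, 0, min(centers), bw / 4),
      upper = c(Inf, max(centers), diff(range(centers)),
                Inf, max(centers), diff(range(centers))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort_bl(
      paste("two-Gaussian fit failed:", conditionMessage(e)),
      "bl_fit_error"))
  if (fit$info == 0 || fit$info == 5)
    abort_bl(sprintf("two-Gaussian fit did not converge (nls.lm info %d: %s)",
                     fit$info, fit$message), "bl_fit_error")
  cf <- fit$par
  rss <- sum(fit$fvec^2)
  comp <- function(i) {
    a <- cf[[paste0("a", i)]]; m <- cf[[paste0("m", i)]]
    s <- cf[[paste0("s", i)]]
    list(mean_pA = m, sd_pA = s,
         weight = a * s * sqrt(2 * pi) / (hist$n_samples * bw))
  }
  c1 <- comp(1); c2 <- comp(2)
  if (abs(c1$mean_pA - baseline_pA) <= abs(c2$mean_pA - baseline_pA)) {
    closed <- c1; open <- c2
  } else {
    closed <- c2; open <- c1
  }
  amp <- open$mean_pA - closed$mean_pA
  # standard errors of the means (Gauss-Newton covariance), for I-V
  # weighting downstream; NA when the Jacobian is degenerate (e.g. a
  # noiseless two-level trace, where the means are exact anyway)
  se <- tryCatch({
    sigma2 <- rss / max(length(counts) - 6, 1)
    covm <- sigma2 * solve(0.5 * fit$hessian)
    sqrt(diag(covm))[c(2, 5)]
  }, error = function(e) c(NA_real_, NA_real_))
  structure(list(closed = closed, open = open,
                 unitary_amplitude_pA = amp,
                 amplitude_se_pA = sqrt(sum(se^2)),
                 rss = rss,
                 fit = fit),
            class = "gaussian_pair_fit")
}

#' @export
print.gaussian_pair_fit <- function(x, ...) {
  cat(sprintf("Gaussian pair fit: closed %.3f pA (sd %.3f, w %.2f); open %.3f pA (sd %.3f, w %.2f)\n",
              x$closed$mean_pA, x$closed$sd_pA, x$closed$weight,
              x$open$mean_pA, x$open$sd_pA, x$open$weight))
  cat(sprintf("  unitary amplitude %.3f pA (se %.3g), RSS %.3g\n",
              x$unitary_amplitude_pA, x$amplitude_se_pA, x$rss))
  invisible(x)
}

#' Plot an all-point histogram with an optional Gaussian-pair overlay
#'
#' @param x an `ap_histogram`.
#' @param fit optional `gaussian_pair_fit` to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ap_histogram <- function(x, fit = NULL, ...) {
  centers <- .hist_centers(x)
  graphics::plot(centers, x$counts, type = "h", xlab = "current (pA)",
                 ylab = "count", ...)
  if (!is.null(fit)) {
    xx <- seq(min(centers), max(centers), length.out = 400)
    g <- function(comp) comp$weight * x$n_samples * x$bin_width_pA /
      (comp$sd_pA * sqrt(2 * pi)) *
      exp(-(xx - comp$mean_pA)^2 / (2 * comp$sd_pA^2))
    graphics::lines(xx, g(fit$closed) + g(fit$open), col = 2, lwd = 2)
  }
  invisible(x)
}
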