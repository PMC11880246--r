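# Two-state gating simulator and trace renderer.

test_that("unitary current follows the ohmic relation", {
  e_ca <- nernst_potential(+2, 150, 15, RTF)
  i <- unitary_current(59.55, -50, e_ca)
  expect_equal(i, 59.55 * (-50 - e_ca) / 1000, tolerance = 1e-12)
  # consistency with the published Gauss-fit amplitude at -50 mV
  expect_equal(i, -4.58, tolerance = 0.05)
  expect_identical(unitary_current(30, 52.77, 52.77), 0)
  expect_equal(unitary_current(27.37, 0, 52.77), -1.444, tolerance = 1e-3)
  expect_error(unitary_current(-1, 0, 0), class = "bl_domain_error")
})

test_that("gating paths are reproducible and tile the duration", {
  m <- channel_model(27.37, 52.77)
  p1 <- simulate_gating(m, 5000, seed = 123)
  p2 <- simulate_gating(m, 5000, seed = 123)
  expect_identical(p1, p2)
  expect_equal(sum(p1$dwell_ms), 5000, tolerance = 1e-9)
  expect_true(all(p1$dwell_ms > 0))
  expect_true(all(diff(p1$state) != 0))  # consecutive states differ
  expect_error(simulate_gating(m, 1000), class = "bl_usage_error")
})

test_that("dwell statistics match the two-state Markov chain", {
  m <- channel_model(27.37, 52.77, k_open_per_s = 15, k_close_per_s = 35)
  p <- simulate_gating(m, 600 * 1000, seed = 99)
  open_frac <- sum(p$dwell_ms[p$state == 1]) / sum(p$dwell_ms)
  p_stat <- 15 / (15 + 35)
  tau <- 1 / (15 + 35)
  se <- sqrt(2 * p_stat * (1 - p_stat) * tau / 600)
  expect_lt(abs(open_frac - p_stat), 3 * se)
  # mean open dwell = 1/k_close (exclude the truncated final dwell)
  open_dw <- head(p$dwell_ms, -1)[head(p$state, -1) == 1]
  expect_lt(abs(mean(open_dw) - 1000 / 35),
            3 * (1000 / 35) / sqrt(length(open_dw)))
  # symmetric rates give open fraction 1/2
  ms <- channel_model(27.37, 52.77, k_open_per_s = 25, k_close_per_s = 25)
  ps <- simulate_gating(ms, 600 * 1000, seed = 4)
  of <- sum(ps$dwell_ms[ps$state == 1]) / sum(ps$dwell_ms)
  expect_lt(abs(of - 0.5), 3 * sqrt(2 * 0.25 / 50 / 600))
})

test_that("dwell times are exponential (KS test at alpha = 0.01)", {
  m <- channel_model(27.37, 52.77, k_open_per_s = 15, k_close_per_s = 35)
  p <- simulate_gating(m, 700 * 1000, seed = 2024)
  st <- head(p$state, -1); dw <- head(p$dwell_ms, -1) / 1000
  open_dw <- dw[st == 1]; closed_dw <- dw[st == 0]
  expect_gte(length(open_dw), 5000)
  expect_gt(stats::ks.test(open_dw, "pexp", 35)$p.value, 0.01)
  expect_gt(stats::ks.test(closed_dw, "pexp", 15)$p.value, 0.01)
})

test_that("multi-channel paths record the summed open count", {
  m <- channel_model(27.37, 52.77, n_channels = 3)
  p <- simulate_gating(m, 20000, seed = 5)
  expect_true(all(p$state %in% 0:3))
  expect_true(all(abs(diff(p$state)) >= 1))
  expect_equal(sum(p$dwell_ms), 20000, tolerance = 1e-9)
})

test_that("rendering reproduces levels, noise statistics and filtering", {
  m <- quiet_model()
  always_open <- structure(data.frame(state = 1L, dwell_ms = 1000),
                           total_duration_ms = 1000, model = m,
                           class = c("gating_path", "data.frame"))
  tr <- render_trace(always_open, m, holding_mV = -50, seed = 1)
  i_unit <- unitary_current(m$conductance_pS, -50, m$e_rev_mV)
  expect_true(all(tr$current_pA == i_unit))
  expect_equal(length(tr$current_pA), 10000)

  # closed-only noisy trace: sample mean near 0
  mn <- channel_model(27.37, 52.77, noise_sd_pA = 0.8,
                      filter_cutoff_Hz = NULL)
  closed <- structure(data.frame(state = 0L, dwell_ms = 10000),
                      total_duration_ms = 10000, model = mn,
                      class = c("gating_path", "data.frame"))
  trn <- render_trace(closed, mn, holding_mV = -50, seed = 8)
  n <- length(trn$current_pA)
  expect_lt(abs(mean(trn$current_pA)), 3 * 0.8 / sqrt(n))

  # low-pass filtering removes noise power at identical seed
  mf <- channel_model(27.37, 52.77, noise_sd_pA = 0.8,
                      filter_cutoff_Hz = 1000)
  trf <- render_trace(closed, mf, holding_mV = -50, seed = 8)
  expect_lt(mean(trf$current_pA^2), mean(trn$current_pA^2))

  # bitwise reproducibility of the full render
  trf2 <- render_trace(closed, mf, holding_mV = -50, seed = 8)
  expect_identical(trf$current_pA, trf2$current_pA)
})

test_that("model invariants are enforced", {
  expect_error(channel_model(0, 0), class = "bl_domain_error")
  expect_error(channel_model(10, 0, k_open_per_s = 0),
               class = "bl_domain_error")
  expect_error(channel_model(10, 0, sampling_rate_Hz = 1500,
                             filter_cutoff_Hz = 1000),
               class = "bl_domain_error")
})

test_that("traces round-trip through TSV + sidecar", {
  m <- channel_model(27.37, 52.77)
  tr <- simulate_trace(m, 200, -50, seed = 31)
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tf, paste0(tf, ".json"))))
  write_trace_tsv(tr, tf)
  tr2 <- read_trace_tsv(tf)
  expect_equal(tr2$current_pA, tr$current_pA, tolerance = 1e-12)
  expect_equal(tr2$sampling_rate_Hz, 10000)
  expect_equal(tr2$holding_potential_mV, -50)
})
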