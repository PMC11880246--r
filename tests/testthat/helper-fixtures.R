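# Shared fixtures: the three bath configurations used throughout, and a
# noiseless square-wave trace builder for exact idealization checks.

RTF <- 25.97  # mV; thermal voltage used for all printed-value checks

kcl_bath <- function(p_cl = 0, rtf = RTF)
  bath_from_salts(c(KCl = 500), c(KCl = 50),
                  permeabilities = c(K = 1, Cl = p_cl), rt_over_f_mV = rtf)

ca_bath <- function(rtf = RTF)
  bath_from_salts(c(CaCl2 = 150), c(CaCl2 = 15),
                  permeabilities = c(Ca = 1), rt_over_f_mV = rtf)

mix_bath <- function(p_ca = 1, rtf = RTF)
  bath_pair(list(ion_species("K", 1, 500, 50, 1),
                 ion_species("Ca", 2, 10, 100, p_ca)),
            rt_over_f_mV = rtf)

# noiseless, unfiltered trace alternating closed/open with the given open
# dwells (ms), separated by closed gaps (ms); amplitude in pA
square_trace <- function(open_dwells_ms, closed_ms = 5, amplitude_pA = -4,
                         fs = 10000, baseline_pA = 0) {
  seg <- function(ms, level)
    rep(level, round(ms / 1000 * fs))
  x <- seg(closed_ms, baseline_pA)
  for (d in open_dwells_ms)
    x <- c(x, seg(d, baseline_pA + amplitude_pA), seg(closed_ms, baseline_pA))
  new_trace(x, fs, holding_mV = -50)
}

quiet_model <- function(g = 27.37, e_rev = 52.77, ...)
  channel_model(g, e_rev, noise_sd_pA = 0, filter_cutoff_Hz = NULL, ...)
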