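# Example pipeline configuration: simulated single-channel recordings in
# an asymmetric 500:50 mM KCl gradient, analyzed end to end.
# Units: mV, pA, pS, mM, ms, K.
mode: simulate
seed: 20260924
duration_s: 30
rt_over_f_mV: 25.97
bath:
  cis:   {KCl: 500}
  trans: {KCl: 50}
  permeabilities: {K: 1.0, Cl: 0.031482}
channel:
  conductance_pS: 27.37
  # e_rev_mV omitted: computed from the bath via the monovalent GHK equation
  k_open_per_s: 15
  k_close_per_s: 35
  noise_sd_pA: 0.8
  filter_cutoff_Hz: 1000
  sampling_rate_Hz: 10000
# voltages_mV omitted: five points bracketing the reversal potential
analysis:
  bin_width_pA: 0.05
  min_open_ms: 1.5
  weighted_iv: false
ghk:
  invert: monovalent
  reference_cation: K
  target_anion: Cl
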