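---
title: "Single-channel bilayer analysis with bilayerlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel bilayer analysis with bilayerlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerlab)
```

## The measurement problem

In a planar lipid bilayer experiment a purified channel protein is
incorporated into an artificial membrane separating two chambers (*cis*,
the protein-addition side, and *trans*). Under voltage clamp, a single
channel produces a telegraph-like current: a closed level ("C") and an
open level ("O") separated by the unitary current *i*. Three quantities
summarize channel behaviour:

* the **unitary conductance** *g*, from the slope of the current--voltage
  (I--V) line, *i* = *g*(*V* − *E*~rev~)/1000 (pA, with *g* in pS and
  potentials in mV);
* the **open probability**, *P*~open~ = *t*~open~/*T*, the fraction of
  the recording the channel spends open;
* the **ionic selectivity**, inferred from the reversal potential
  *E*~rev~ measured under asymmetric solutions, via the Nernst and
  Goldman--Hodgkin--Katz (GHK) voltage equations.

bilayerlab implements this chain end to end — idealization, amplitude
histograms, I--V fitting, electrochemical inversion — together with a
seeded simulator that renders traces with the statistical structure the
analysis assumes, so every estimator can be validated against known
ground truth.

## Electrochemistry

For a single permeant ion with valence *z*, the Nernst equilibrium
potential is $E = (RT/zF)\,\ln(c_\mathrm{out}/c_\mathrm{in})$. With
several monovalent permeant species, the GHK voltage equation gives

$$E_{rev} = \frac{RT}{F}\ln
\frac{\sum_\mathrm{cat} P\,c_\mathrm{out} + \sum_\mathrm{an} P\,c_\mathrm{in}}
     {\sum_\mathrm{cat} P\,c_\mathrm{in} + \sum_\mathrm{an} P\,c_\mathrm{out}}.$$

For a mixture of a monovalent cation X⁺ and a divalent cation Y²⁺ the
constant-field derivation yields an *implicit* equation in
$u = e^{E_{rev}F/RT}$:

$$E_{rev} = \frac{RT}{F}\ln
\frac{P_X[X]_\mathrm{out}(1+u) + 4P_Y[Y]_\mathrm{out}}
     {P_X[X]_\mathrm{in}(1+u) + 4P_Y[Y]_\mathrm{in}\,u},$$

which `ghk_reversal_extended()` solves by bracket-scanned bisection on
[−500, 500] mV to a residual below 10⁻¹⁰ mV (bisection was chosen over
faster root finders for unconditional robustness at this problem size;
multiple sign changes in the scan raise an explicit ambiguous-root
error). Conversely, with *E*~rev~ measured, the equations are solved in
closed form for one unknown permeability:
`invert_monovalent_ratio()` uses
$P_\mathrm{an}/P_\mathrm{cat} = (c_\mathrm{cat,out} - u\,c_\mathrm{cat,in})/(u\,c_\mathrm{an,out} - c_\mathrm{an,in})$,
and `invert_divalent_ratio()` exploits that the divalent equation is
linear in $P_Y$ once *u* is fixed. Every inversion is verified on the
spot by re-evaluating the forward equation at the solved ratio
(agreement within 10⁻⁶ mV is enforced as an invariant of the result
object).

Design choices worth knowing:

* **Orientation.** "out" ≡ *cis* and "in" ≡ *trans*. With 500 mM KCl on
  the *cis* side this is the only mapping under which a cation-selective
  channel reverses at a *positive* potential, as observed.
* **Divalent anion terms.** The divalent equation excludes anion terms
  by default, mirroring its usual bi-ionic form. With
  `include_anions = TRUE` they are added carrying the same (1+*u*)
  factor as the monovalent cations, the one placement under which the
  equation reduces *exactly* to the monovalent GHK equation when the
  divalent concentrations go to zero.
* **Thermal voltage.** Temperature defaults to 298.15 K but RT/F can be
  set directly. The package's validation suite uses RT/F = 25.97 mV
  (T ≈ 301.4 K), the unique value under which the two published
  (*E*~rev~, *P*~K~/*P*~Cl~) pairs for this channel — (52.77 mV, 31.77)
  and (46.96 mV, 15.38) — are simultaneously self-consistent; this
  consistency is itself an executable test.
* **Concentrations, not activities.** Permeability ratios use nominal
  concentrations; activity coefficients, liquid-junction corrections and
  surface-charge effects are out of scope. (This is also why the K⁺
  equilibrium potential of a 500:50 mM gradient computes to ≈ 59.8 mV
  rather than a lower activity-corrected value.)

```{r}
b <- bath_from_salts(c(KCl = 500), c(KCl = 50), rt_over_f_mV = 25.97)
invert_monovalent_ratio(52.77, b)
```

## The trace simulator

No public raw bilayer recordings exist for this channel, so the
generator stands in for them. It emulates exactly the features the
analysis relies on, with each element configurable via
`channel_model()`:

* **Gating**: a two-state (closed/open) continuous-time Markov chain
  with rates `k_open_per_s` and `k_close_per_s`; dwell times are
  exponential, the long-run open fraction is
  $k_\mathrm{open}/(k_\mathrm{open}+k_\mathrm{close})$. Defaults are
  15 s⁻¹ and 35 s⁻¹, i.e. *P*~open~ = 0.3 and a mean open dwell of
  ≈ 29 ms, far above the 1.5 ms dead time so that dead-time censoring
  is negligible. Multiple independent channels are supported; the path
  then records the instantaneous open count and the analysis reports
  NPo.
* **Unitary current**: ohmic, *i* = *g*(*V* − *E*~rev~)/1000, with the
  reversal potential supplied directly or computed from a bath recipe.
* **Noise and filtering**: additive white Gaussian noise (default SD
  0.8 pA) added to the ideal trace, then a causal 4-pole Butterworth
  low-pass at 1 kHz, sampled at 10 kHz — the order of operations of an
  amplifier/filter/digitizer chain. The hardware being emulated
  specifies only a 1--2 kHz corner; the Butterworth order, the corner
  and the noise SD are package choices, not recorded facts.
* **Sampling**: events are realized on the continuous time axis and
  then point-sampled; events shorter than the sampling interval can
  vanish, as in real acquisition.

The generator deliberately omits baseline drift, 1/f noise, capacitance
transients, subconductance levels and the amplitude saturation seen at
millimolar Ca²⁺ (no functional form for it is established). Passing
recovery tests on simulated data therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
artifact of real recordings.

All randomness is seeded: identical (model, duration, seed) gives
bitwise-identical paths and traces, and pipeline runs derive per-stage
seeds from one master seed.

## Idealization and open probability

`idealize()` applies the field-standard half-amplitude criterion: a
threshold at baseline + 0.5 × unitary amplitude assigns each sample
open or closed, runs become events, and open events shorter than the
dead time (default 1.5 ms) are merged back into the flanking closed
level — "ignored", so they contribute neither an event nor open time.
The merge (rather than deletion) preserves the invariant that events
tile the trace. A symmetric closed-gap dead time is available but off
by default, since only the open-time rule is part of the published
procedure. The threshold criterion itself is a package choice; the
acquisition software used for the original recordings does not document
its detection criterion.

The baseline is the mode of the dominant all-point-histogram peak,
refined by an iterated symmetric windowed mean (window = 2 × the peak's
half-width at half-maximum). The iteration converges to the center of
the closed-level peak, is insensitive to the open-level peak, and for a
pure Gaussian closed level is nearly as efficient as the sample mean;
it falls back to the median if no peak is identifiable. Because the
baseline is re-estimated per trace, idealization is invariant to a
constant current offset.

`open_probability()` is the plain ratio of open time to trace duration.
Sub-dead-time openings reduce it by construction; at the default rates
this bias is below 0.2% of *P*~open~.

## Amplitude histograms and the I--V line

`all_point_histogram()` bins every sample (default bin width 0.05 pA —
unreported in the original workflow, so configurable), and
`fit_amplitude_gaussians()` fits the sum of two Gaussians to the bin
counts by Levenberg--Marquardt least squares, initialized at the two
tallest histogram peaks. Peak detection requires 0.5 pA separation, a
minimum height (5% of the tallest peak) and a genuine valley between
peaks, which rejects shot-noise bumps on the shoulder of a single
level; a unimodal histogram raises a typed degenerate-fit condition
carrying the single-component fit. Fitting binned counts (rather than
EM on raw samples) matches standard acquisition-software practice and
is deterministic. Exactly two components are fit — traces here show one
open level — and the signed unitary amplitude is mean(open) −
mean(closed).

`fit_iv()` fits the straight line *i* = *aV* + *b* by ordinary (or
inverse-variance weighted) least squares: conductance = 1000*a* pS,
*E*~rev~ = −*b*/*a* with a delta-method standard error. A linear I--V
is assumed throughout; rectification models are out of scope.
`build_iv()` assembles the dataset from per-trace Gaussian fits,
pooling duplicate voltages by inverse variance.

## The pipeline

`run_pipeline()` composes the whole chain from one YAML/list config
(see `system.file("extdata", "example_config.yaml", package =
"bilayerlab")`): simulate (or load TSV) traces at each voltage →
analyze each → I--V fit → GHK inversion at the fitted *E*~rev~. It
writes trace TSVs, event CSVs and a report JSON whose every number is
traceable to a per-stage artifact, and it is byte-reproducible for a
given config. A thin command-line wrapper over these functions ships in
`inst/cli/bilayerlab.R`.

```{r, eval = FALSE}
cfg <- system.file("extdata", "example_config.yaml", package = "bilayerlab")
report <- run_pipeline(cfg, out_dir = "results")
report
```

The simulation protocol used for validation places five voltages at
*E*~rev~ + {−110, −80, −50, +50, +80} mV: a ≥ 100 mV span that brackets
the reversal potential while keeping the smallest unitary current
(≈ 1.4 pA at the smallest conductance studied) well above the filtered
noise floor (≈ 0.36 pA SD after the 1 kHz filter), so the two histogram
peaks remain resolvable at every voltage. Validation runs use 60 s
traces per voltage (the suite uses shorter ones where only structure is
being checked); at these sizes the pipeline recovers conductances of
27--60 pS to well within 5% and reversal potentials within 2 mV.

## Numerical and degenerate-input behaviour

* GHK solvers reject baths whose species fall outside the supported
  valences and report no-solution / ambiguous-root errors explicitly.
* Inversions at the edge of the attainable *E*~rev~ window return the
  limiting ratio (0 or ∞) exactly at the boundary and a typed
  no-solution error beyond it; floating-point dust just outside the
  boundary (|P| < 10⁻⁹) is clamped to zero.
* Noiseless two-level traces produce delta-like histograms; the
  Gaussian fit then pins the means to the correct bin centers while the
  component widths are unidentifiable (their standard errors are
  reported as NA).
* Exactly collinear I--V points are fit exactly, with zero residuals
  and zero standard errors.

## Known limitations

* Two-state gating only; no burst analysis, hidden-Markov idealization
  or missed-event correction beyond the fixed dead time.
* Ohmic I--V only; no GHK current-equation fitting.
* Selectivity results inherit all assumptions of the GHK framework
  (independence, constant field, concentrations for activities).
* The divalent inversion requires exactly one unknown permeability;
  near the reversal potential where the unknown becomes unidentifiable
  the closed form degenerates and a no-solution error is raised.
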