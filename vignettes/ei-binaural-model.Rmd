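---
title: "An excitatory-inhibitory coincidence model for electric and acoustic binaural hearing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An excitatory-inhibitory coincidence model for electric and acoustic binaural hearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdsim)
```

## The model

`itdsim` simulates one binaural model neuron of the lateral-superior-olive
(EI) type: it is excited by auditory-nerve (AN) fibers from the ipsilateral
ear and inhibited by fibers from the contralateral ear, and its firing rate
as a function of the interaural time difference (ITD) or interaural phase
difference (IPD) is the quantity of interest. The same neuron is driven
either by a stochastic model of the *electrically* stimulated auditory
nerve (cochlear-implant biphasic pulse trains on one electrode per ear) or
by a simplified *acoustic* periphery responding to high-frequency,
amplitude-modulated stimuli. Because both pathways converge on the
identical binaural stage, differences between electric and acoustic
rate-ITD behavior can be attributed to the periphery, and similarities to
the EI interaction itself.

### The EI coincidence counter

The binaural neuron is a deterministic coincidence counter
(`ei_params()`, `simulate_ei()`). At every pooled excitatory spike time
`t` it forms the net count

    count(t) = #{excitatory spikes in (t - w_exc, t]}
               - g_inh * #{inhibitory spikes in (t - w_inh, t]}

and fires when `count >= threshold`, subject to an absolute refractory
period. Defaults: `w_exc` = 1.1 ms, `w_inh` = 3.1 ms, `threshold` = 3,
`g_inh` = 2, `t_ref` = 1.6 ms, with 20 excitatory and 8 inhibitory input
fibers. Two structural consequences follow directly:

* **The trough is not at zero ITD.** The response minimum occurs where the
  (shorter) excitation is centred inside the (longer) inhibition, i.e.
  with inhibition leading by about `(w_inh - w_exc)/2`; with the
  contralateral-leading-positive sign convention the trough sits at a
  small positive ITD, and the suppressed region spans about
  `w_inh - w_exc` = 2 ms.
* **Full entrainment defeats inhibition.** When every input fires on every
  cycle, the net count is `20 - 2 x 8 = +4 >= 3`: at high stimulation
  levels the neuron fires once per cycle regardless of ITD, so ITD tuning
  flattens out.

The windows are trailing (causal) rectangles, counts are evaluated only at
excitatory event times (simultaneous spikes form one evaluation), the
window boundary is half-open `(t - W, t]`, and refractoriness is absolute.
A brute-force quadratic reference implementation (`ei_oracle()`) evaluates
the same rule by direct window-membership tests and is compared
spike-for-spike against the fast event-driven path on 1000 random
ensembles in the test suite.

### The electric periphery

`simulate_electric_fiber()` implements a stochastic single-fiber model
with four stages: (1) leaky-integrator charging by the first pulse phase,
`u = I g (1 - exp(-t_phase/tau_m))` with `tau_m` = 100 us and
`t_phase` = 100 us; (2) additive zero-mean Gaussian membrane noise with SD
`relative_spread x v_threshold`, so the single-pulse firing probability is
the Gaussian tail of the margin; (3) refractoriness: firing is impossible
within `t_abs` = 0.7 ms of the last action potential and the threshold is
elevated by `1/(1 - exp(-(dt - t_abs)/tau_rel))`, `tau_rel` = 1.32 ms,
afterwards; (4) the recorded spike time adds a latency draw
(0.685 +/- 0.1 ms) and a jitter draw. There is no adaptation across
pulses, and all fibers share one threshold.

Two parameter choices deserve explanation:

* **`relative_spread` = 0.19.** The reference current (0 dB thr) is
  defined functionally: the smallest current of a 40-pps standard train at
  which ipsilateral-only stimulation makes the EI neuron fire at least
  1 sp/s (`find_reference_threshold()`). That definition places 0 dB thr
  at a single-pulse firing efficiency of only a few percent. The
  population-level behaviors this package reproduces — AN rate-level functions that
  flatten near 10 dB thr, ITD tuning that is present at 5 dB thr and gone
  above ~10 dB thr — require the firing-efficiency sigmoid to span roughly
  8-10 dB above that reference, which fixes the noise spread near 0.19. A
  much smaller spread would saturate every fiber within ~2.5 dB of the
  reference and erase the level dependence entirely.
* **Efficiency-dependent jitter.** Jitter is not constant: spikes
  triggered at a large margin above (possibly refractoriness-elevated)
  threshold are precise (`jitter_sd_min` = 0.06 ms), while spikes
  triggered at vanishing margin are sloppy (`jitter_sd_max` = 0.35 ms),
  interpolated linearly in the effective firing efficiency of the
  triggering pulse. This mirrors the firing-efficiency dependence of
  latency jitter measured in electrically stimulated cat fibers, and it
  matters qualitatively: near-threshold and high-rate (refractoriness-
  limited) responses de-synchronize, while high-level low-rate responses
  entrain with sub-0.1-ms precision.

The voltage gain `g` = 4.28e-3 per uA is the single calibration constant
of the electric pathway; it was chosen once so that
`find_reference_threshold("unmodulated")` returns approximately 240 uA,
and is stored in the defaults. With the same calibration the 40-Hz SAM
1000-pps reference comes out near 222 uA — lower than the unmodulated
reference, as expected from the larger number of near-peak pulses per
cycle, but not as low as the 130 uA a model with slower membrane
integration would give: with `tau_m` = 100 us there is no charge summation
across 1-ms inter-pulse gaps. Levels of SAM trains in this package are
therefore expressed relative to the package's own derived SAM reference,
which keeps "dB thr" physiologically meaningful.

### The acoustic periphery

The acoustic stage (`simulate_acoustic_fiber()`) is an intentionally
simple stand-in with a narrow interface (stimulus in, spike ensemble out)
so that a full published periphery can be substituted. The chain is:
4th-order gammatone filter at CF (bandwidth on the standard ERB scale,
`24.7 (4.37 CF/1000 + 1)` Hz); half-wave rectification plus first-order
1-kHz low-pass (inner-hair-cell stage); logarithmic level-to-rate
compression mapping the instantaneous drive (in dB re the drive of a CF
tone at 0 dB SPL) onto `[spont_rate, rate_max]` = [5, 250] sp/s with slope
`rate_slope` = 0.03 per dB; subtractive single-exponential adaptation
(`tau` = 60 ms, strength 0.5); and an inhomogeneous-Poisson spike
generator with a 0.75-ms dead time. All fibers are medium-spontaneous-rate
(0.5-18 sp/s) with CF equal to the stimulus carrier.

`rate_slope` is the one tuned constant of this stage: it was set so that
the EI neuron's peak response to SAM tones is largest near 30 dB SPL
(saturation begins ~33 dB above fiber threshold), the anchor level used
throughout the acoustic protocols. What this stand-in reproduces is the
*envelope coding* that the binaural analyses depend on: spontaneous-rate
recovery in silence, monotone-then-saturating rate-level functions,
phase locking to the modulator that is stronger for sharp-envelope stimuli
(filtered clicks, Gaussian-envelope tones) than for SAM and transposed
tones, and modulation locking that collapses as the modulation frequency
approaches the auditory-filter bandwidth. What it does **not** attempt:
two-tone suppression, power-law adaptation, spontaneous-rate classes,
level-dependent phase shifts, or quantitative spike rates of a full
biophysical periphery — absolute acoustic rates here are indicative only.

## Stimuli

Four acoustic classes, all 1 s long with 10-ms sin^2 gating and the
steady-state RMS scaled to the requested dB SPL (`apply_gating_and_level()`
is idempotent and shared by all generators):

* **SAM tones** — `sin(2 pi f_c t)(1 - cos 2 pi f_m t)`: three spectral
  lines at `f_c`, `f_c +/- f_m` in ratio 1:1/2:1/2.
* **Transposed tones** — a half-wave-rectified `f_m` sine, low-passed
  (4th-order Butterworth at 2 kHz, zero-phase), peak-normalized, on an
  `f_c` carrier: the envelope is "off" half of each cycle.
* **Gaussian-envelope (GE) tone trains** — Gaussian pulses whose
  equivalent rectangular bandwidth (amplitude convention, so
  ERB x ERD = 1) equals the frequency extent of 1.5 mm of cochlea at the
  carrier place under the human Greenwood map (A = 165.4 Hz,
  a = 0.06 /mm, k = 1): 1695 Hz and 0.59 ms at 8 kHz, matching the
  printed 1691 Hz / 0.6 ms pair to within the rounding of the Greenwood
  constants. Carrier phase is locked to each pulse centre.
* **Filtered click trains** — 10-us condensation clicks through a
  2nd-order constant-Q = 0.5 Butterworth band-pass (corners
  `f_c (sqrt(1 + 1/(4Q^2)) -/+ 1/(2Q))`), synthesized at 200 kHz so the
  click spans two samples.

Electric stimuli are biphasic (cathodic-first, 100-us phase) pulse trains,
600 ms with 10-ms sin^2 amplitude gating sampled at the pulse times,
either unmodulated or with the raised-cosine SAM envelope
`(1 - cos 2 pi f_m t)/2` on a 1000- or 5000-pps carrier (`f_m` at most
40 % of the carrier rate). Pulses sit at `(k + 1/2)/rate` so the first
pulse clears the onset ramp; currents are `I_ref 10^(level/20)`.

ITDs are applied to the contralateral *spike trains* rather than the
stimuli (`apply_itd()`; positive = contralateral-leading), so one
periphery simulation serves an entire ITD/IPD grid. For IPD grids the
shift is `IPD/(2 pi f_m)`, which at low modulation frequencies exceeds
4 ms — the 4-ms cap applies to ITD-axis grids only.

## Analyses

`firing_rate()` (acoustic window 0.2-1 s, discarding the onset response;
electric window 0.01-0.6 s, excluding the onset ramp), `psth()` (1-ms
bins), `period_histogram()` (50 bins by default), `vector_strength()`
(`|mean exp(i phi_k)|`), `ac_dc_ratio()` (non-DC RMS over DC of the
rectified waveform, computed from FFT amplitudes), tuning curves over
ITD/IPD grids with per-repetition rates (`ei_tuning_curve()`, tidied via
`tidy()`/`glance()`), the best-worst contrast `sqrt(r_max) - sqrt(r_min)`
(`sqrt_contrast()`; a Poisson-motivated discriminability proxy, since the
deterministic EI stage produces unrealistically low across-trial
variance), and curve similarity as the squared Pearson correlation of two
*mean* curves on a common grid (`r_squared()`; means rather than pooled
repetitions, a documented choice). Two geometric measurements support the
headline analyses: `trough_span()` (contiguous span around the worst ITD
below a fraction — default 20 % — of the curve maximum) and
`second_plateau_offset()` (distance from the worst ITD to the onset of
the doubled-rate plateau; onset at `2 f_m`, or at 95 % of the curve
maximum when the upper plateau does not reach `2 f_m` — see Limitations).

The rate limit of ITD sensitivity is operationalized by `cutoff_rate()`:
the highest tested rate at which the contrast still reaches half its
maximum over the rate list `[25 50 100 200 250 320 400 500 800]`. The
analytic limit is `1/w_inh` (323 per second at the 3.1-ms default):
once the stimulation or modulation period is shorter than the inhibitory
window, inhibition from successive cycles merges and the trough fills in.

## Reproducibility and problem sizes

Every stochastic step takes a seed; populations and repetitions derive
child seeds with a counter-based rule (`derive_seed()`), so
`run_experiment()` re-runs byte-identically, and any single condition can
be reproduced in isolation from the provenance JSON. Default repetition
counts follow the protocol conventions: 10 repetitions for acoustic
rate-ITD curves, 20 for electric and cross-modal comparisons. The test
suite and the acceptance script use the full grids (81 ITD points at
0.1 ms, 41 IPD points at 0.05 pi) at those repetition counts; the single
deliberately reduced instance is the oracle cross-check, which uses 8-ms
ensembles of at most 30 spikes so the quadratic reference stays cheap
across 1000 cases.

## Limitations and known disagreements

* **Trough depth of low-rate electric tuning curves.** With 20 excitatory
  against 8 double-weighted inhibitory fibers and threshold 3, the net
  count at the worst ITD has mean `4p` (p = per-pulse firing probability)
  and standard deviation of about `sqrt(52 p(1-p))` across independent
  fibers, so the trough rate never falls below roughly a quarter of the
  peak at any level: the architecture suppresses, but cannot silence, the
  response of independent, binomially firing inputs. The 2-ms trough
  *width* is reproduced exactly; a trough deeper than 20 % of the maximum
  at 5 dB thr is not attainable and the corresponding acceptance check is
  left failing rather than re-defined.
* **Rate-limit cutoffs for pulse-locked electric input.** Above
  `1/w_inh`, rectangular windows covering an integer-plus-fraction number
  of pulse periods alternate between 1 and 2 covered inhibitory volleys,
  which *revives* IPD tuning at some rates instead of letting it collapse
  smoothly. A non-rectangular (e.g. exponential or alpha-function)
  inhibitory kernel would remove this artifact; with the rectangular
  window the half-maximum cutoff is not strictly monotone in `w_inh` for
  electric stimuli, and that acceptance check is left failing where the
  model genuinely disagrees.
* **Upper plateau level at high acoustic levels.** The stand-in
  periphery's click response at 70 dB SPL spans about 2.7 ms — long
  enough for *probabilistic* second EI responses per cycle (upper plateau
  near 1.45x the pulse rate) but not for certain ones (2x). The
  plateau-onset geometry (about 3.2-3.3 ms below the worst ITD, set by
  the refractory period plus the trough offset) is reproduced; its
  absolute level is not, which is why `second_plateau_offset()` carries
  the documented 95 %-of-maximum fallback.
* The SAM reference threshold derives to ~222 uA rather than 130 uA (see
  the electric-periphery section); inhibitory and excitatory pathways
  share the periphery latency (no extra synaptic delay), which may shift
  trough positions slightly; and there is no spread of excitation across
  electrodes, no fiber-to-fiber threshold variance, and no
  conductance-based dynamics — all deliberate simplifications.

## A worked example

```{r example, eval = FALSE}
library(itdsim)

# rate-ITD curve of the EI neuron for a 50-pps pulse train at 5 dB thr
train <- gen_electric_train(50, level = 5)
curve <- ei_tuning_curve(train, axis = "itd", n_reps = 20, seed = 1)
glance(curve)
autoplot(curve)

# the analytic rate limit of ITD sensitivity at the default window
round(1 / ei_params()$w_inh) # 323 per second
```
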