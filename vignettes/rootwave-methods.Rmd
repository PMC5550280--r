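---
title: "Analysing optogenetically perturbed fictive locomotion with rootwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing optogenetically perturbed fictive locomotion with rootwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootwave)
```

## The problem

In the isolated neonatal mouse spinal cord, NMDA and serotonin evoke
locomotor-like activity: slow (~0.3–0.6 Hz) rhythmic bursting recorded from
the lumbar ventral roots, with ~180° alternation between the bilateral
flexor-dominated roots (L1/L2) and between ipsilateral flexor- and
extensor-dominated roots (L1/2 vs L5/6). Optogenetic silencing or excitation
of motoneurons during a 60-s light epoch perturbs this rhythm: firing is
suppressed by tens of percent, the cycle frequency drops transiently by
roughly 5–13% and recovers within the light, the inter-root phase shifts by
tens of degrees, and both frequency and firing rebound when the light goes
off.

`rootwave` implements the complete quantification pipeline for such
experiments — trial container and preprocessing, wavelet-based frequency and
phase extraction, baseline normalization and per-experiment aggregation, and
pointwise bootstrap comparison of two cohorts — together with a synthetic
generator of fictive-locomotion trials with known ground truth, used for
calibration and for end-to-end parameter-recovery testing.

## Trial protocol and preprocessing

A trial is a 3-min multichannel recording (60 s pre-light, 60 s light, 60 s
post-light; 5 or 10 kHz acquisition). All trials are aligned to the light
onset by trimming 5 s at each end ([align_trim()]): the working record is
170 s with the light at [55, 115) s. All windows in the package are
half-open `[a, b)`, in seconds from the start of the (trimmed) record.

Two filter chains, both 4th-order Butterworth run forward–backward
(zero-phase; the underlying analysis is phase-critical, and cutoff
frequencies — 200, 10, 5, 0.01 Hz — are protocol constants, while order and
realization are the package's choices):

* **Integrated neurogram** ([integrate_neurogram()]): low-pass 200 Hz →
  high-pass 10 Hz → full-wave rectification → low-pass 5 Hz. This is the
  classic rectified-and-smoothed multiunit envelope, a proxy for pooled
  motoneuron firing. Small negative undershoots of the final stage are
  clipped to zero so the trace is an envelope.
* **Slow locomotor drive potential** ([extract_slow_potential()]): low-pass
  200 Hz → band-pass 0.01–5 Hz. A direct 4th-order recursion at 0.01 Hz is
  numerically unstable at kilohertz rates (pole radii within ~1e-5 of the
  unit circle), so the low-frequency edge is realized by estimating the
  sub-0.01-Hz baseline on a ~19-Hz decimated copy — alias-free, because the
  trace is already limited to 5 Hz — with 100 s of reflective padding, then
  interpolating it back and subtracting. The result is zero-mean over long
  windows, as a band-passed trace must be.

Light-on/off step artifacts of continuous illumination are removed by
[correct_step_artifact()]: the baseline on each side of a transition is
estimated from the medians of the thirds of a 200-ms window, extrapolated
quadratically to the transition instant. Medians reject spikes; the
quadratic absorbs the local slope and curvature of the rhythm, so only the
true DC step is subtracted. Pulse-train artifacts are removed by averaging
a fixed window around every pulse onset and subtracting the averaged
template ([subtract_pulse_artifacts()]); the window is capped at the
inter-pulse interval, and fewer than 10 pulses yield a warned no-op since
the template would be dominated by signal.

## Wavelet frequency and phase

The slow potentials carry the rhythm. [cwt_spectrogram()] computes a
complex Morlet continuous wavelet transform (centre parameter ω₀ = 6) on 64
log-spaced frequencies over 0.1–2 Hz, with exactly **3200 points along the
time dimension** spanning the 170-s record (~18.8 Hz, the "19-Hz" common
time base). Because the slow potential is band-limited to 5 Hz by its own
chain, interpolating it onto the 3200-point base before the transform is
alias-free and gives coefficients identical (to numerical tolerance over
this grid) to transforming at the native rate and resampling — at a small
fraction of the cost. The cone of influence (envelope e-folding time,
√2·scale per frequency) is recorded.

* **Instantaneous frequency** ([ridge_frequency()]): at each time point,
  the frequency of maximal wavelet power within the band. The 64-point log
  grid steps by 4.9%, which is coarser than the ~8% frequency drops being
  measured, so the argmax is refined by 3-point parabolic interpolation of
  log-power across log-frequency. Where the ridge power falls below 5% of
  the trial's median ridge power the frequency is set to 0 — the input to
  the trial-discard rule.
* **Inter-root phase** ([pair_phase()]): the phase of the cross-wavelet
  spectrum `A·Conj(B)` read along the joint ridge (maximum cross-power;
  ties resolved toward the lowest frequency), wrapped to (−180°, 180°].
  The same joint ridge provides the pair's frequency series, which is what
  the pipeline uses as the trial's rhythm frequency (a per-pair estimate;
  a single-reference-root variant is just `ridge_frequency` on one
  channel's spectrogram).

Wavelet edge effects motivate clipping 10 s at each end of every derived
series ([clip_edges()]; values are kept, an `analyzed` mask marks the
usable [10, 160) span — 2823 of the 3200 points). A trial is **discarded**
([check_validity()]) when its ridge frequency hits 0 anywhere in the
clipped pre-light or light span; post-light dropouts do not discard. Note a
genuine limitation: with ω₀ = 6 the wavelet envelope spans ~2 s at 0.45 Hz,
so silent gaps much shorter than ~10 s retain smeared power from their
flanks and need a stricter (configurable) threshold to be caught.

## Normalization, aggregation, window summaries

To compare across trials and animals ([normalize_frequency()],
[normalize_phase()], [normalize_firing()]):

* frequency: `100·(f(t)/f̄_control − 1)` (% change; control mean 0),
* phase: circular mean over the control window subtracted on the circle,
  absolute value kept (degrees, [0, 180]),
* firing: the integrated neurogram resampled at 19 Hz, resized linearly to
  the 3200-point base, then `100·(y(t)/ȳ_control − 1)`.

The control window is [10, 55) s of the trimmed record — the full clipped
pre-light span. Exact bounds are not protocol constants; the choice
maximizes the baseline sample and is configurable. Phase baselines use the
circular mean because wrapped phases near ±180° would make an arithmetic
mean meaningless.

Per experiment, series are averaged pointwise over valid trials only, and
experiments with fewer than **three valid trials** are excluded with a log
message ([average_experiment()]). [window_summary()] reports the four
standard 10-s means — control (the 10 s before the light), start-light,
end-light, after-light — taken flush against the light transitions; the
wavelet's temporal smearing near the onset is deliberately not compensated.
A `stat = "max"` variant reports the extremum per window, used for
pulse-train (excitation) protocols where the peak change is the quantity of
interest.

## Bootstrap group comparison

[bootstrap_ttest_series()] compares two cohorts of experiment-averaged
series (matrices of 3200 time points × experiments). Per time point it
computes the Welch t statistic and a two-sided bootstrap p-value with
**10,000 iterations** by default: each group's columns are re-centred on
the pooled mean (shift-method null), whole experiments are resampled with
replacement within each group, and one resample per iteration is shared
across all 3200 points — the resampling unit is the experiment, never the
time point, preserving within-series autocorrelation. `p = (1 + #{|t*| ≥
|t_obs|})/(n_iter + 1)`; a "pooled" percentile null is selectable. With
10,000 iterations the smallest attainable p is 1/10001, just below the
10⁻⁴ display tier. If a resample makes both groups constant with unequal
means the statistic is infinite and counts as an exceedance. Significance
is displayed in the conventional tiers (green p<0.05, yellow p<0.01,
orange p<0.001, red p<0.0001, strict inequalities;
[tier_significance()], [render_comparison()]). No multiple-comparison
correction is applied across the 3200 points — the bands are descriptive,
matching how such pointwise comparisons are conventionally displayed.

A small-cohort caveat: resampling whole experiments makes the null
heavy-tailed when groups are small — near-degenerate resamples (few
distinct experiments) produce huge |t*|, and with n = 6 per group the
all-one-column draw alone has probability ~2·6⁻⁵ ≈ 3·10⁻⁴, putting the
p < 0.0001 tier out of reach no matter how large the true effect. Tiered
maps should be read with the cohort size in mind; at the 25-vs-28 scale
the package's recovery study runs, the deepest tier is attainable and
reached across most of the light epoch for the firing comparison.

Type-I calibration (see the test suite) uses 100 replicate pairs of null
cohorts (10 vs 10 experiments) built by the series-level generator
[synth_rhythm_series()] — the generative frequency model plus autocorrelated
measurement noise, fed through the package's own normalize/average path —
at 1,000 iterations; the fraction of sub-0.05 points is 0.05 ± 0.02.
Hundreds of full raw-signal cohorts would measure the same property at
vastly higher cost; the raw path is exercised end-to-end in the
parameter-recovery study instead.

## The synthetic generator

[synthetic_scenario()] / [generate_trial()] emulate the statistical
structure the pipeline assumes, with full ground truth. Per experiment, a
base frequency is drawn from N(0.45, 0.06) Hz and all effect sizes are
jittered by a mean-one lognormal (sdlog 0.15; animals differ in effect
magnitude, and published cohort SDs are of this order). Per trial, the true
frequency trajectory f(t) applies a fractional drop at light onset (peak
0.08) recovering exponentially within the light (τ = 30 s, so the drop has
largely recovered by light-off), and an additive rebound at light-off (peak
0.13, τ = 10 s). The instantaneous phase Φ(t) = ∫f dt drives each channel's
raised-cosine burst envelope (duty cycle 0.5 — roughly half-cycle bursts)
at its phase lag (bilateral flexors and ipsilateral flexor–extensor pairs
in antiphase). During the light the envelope is scaled by 1 − suppression
(flexor 0.63, extensor 0.78) with slow exponential recovery (τ = 130 s,
i.e. only partial within-light recovery), and transient per-channel phase
offsets realize pair-level phase shifts (bilateral 24°, ipsilateral 55°
peak, τ = 30 s). After the light, firing rebounds (peak 0.40, τ = 10 s).

The carrier is an inhomogeneous Poisson spike train convolved with a 3-ms
biphasic unit waveform — so the 10-Hz high-pass of the integration chain
passes burst structure while the waveform carries no DC — amplitude 1 mV,
peak rate 20 Hz, over 0.5 µV Gaussian electrode noise, **plus a 20-µV slow
drive potential** proportional to the burst envelope and attenuated at half
the firing suppression. The drive component is essential, not decorative:
biphasic spikes have no power below 5 Hz, so without it the slow-potential
chain would see only noise — physiologically it is the population synaptic
drive visible under the spikes in real root recordings. The carrier is
deliberately sparse-and-large rather than dense-and-small: the rectified
envelope is proportional to spike rate only in the sparse regime (the
zero-phase filters ring for tens of milliseconds, and overlapping ringing
partially cancels under rectification), and the analysis — like the
experimental literature — treats the integrated neurogram as a firing
proxy. Both regimes exist in real data; the generator's defaults document
the assumption rather than hide it. Band-limited-noise and deterministic
rate carriers are selectable for calibration tests.

Synthesis runs at 1 kHz by default (a generator parameter, not acquisition
metadata): every analysed structure lies below the 200-Hz filter stage,
and this keeps paper-scale cohorts (25 + 28 experiments × 4 trials)
tractable on a laptop. `fs = 5000` reproduces the acquisition-rate
geometry exactly when needed.

**Ground truth.** Each trial carries its true frequency trajectory, per
channel firing-rate envelope and modulation, true pairwise phase
trajectories — and the *pair-level instantaneous frequency*, which is the
CPG frequency plus the mean drift of the two channels' transient phase
offsets. A moving phase lag is a genuine transient frequency excursion of
the measured signals, so recovery comparisons must use the pair-level
truth; charging it to the estimator would be a bookkeeping error.
[truth_window_summaries()] maps the truth onto the trimmed time base and
computes the same normalized window summaries the pipeline estimates, so
parameter recovery compares like with like.

What the generator does **not** emulate: chloride-reversal phase flips
(only phenomenological phase offsets), biophysical CPG dynamics,
non-stationary baseline drift, line noise, electrode artifacts other than
light steps and pulse templates. Passing recovery tests therefore shows
the pipeline is faithful under the stated statistical structure, not that
it is robust to every pathology of real recordings.

## Known measurement biases (quantified in the tests)

Two biases are inherent to this analysis and are documented rather
than compensated:

* **Onset smearing of the frequency drop.** The ω₀ = 6 Morlet averages
  ~±2 s around each time point at 0.45 Hz. A 10-s start-light window taken
  flush against the onset therefore loses part of the drop to the smeared
  transition; the group-mean start-light frequency change under-recovers
  its ground-truth value by roughly 10–15% relative. The same smearing
  makes frequency/phase changes appear to begin slightly *before* the
  light onset in averaged plots.
* **Rectified-envelope compression.** Even in the sparse regime the
  integrated neurogram is mildly sublinear in spike rate (filter-ringing
  cancellation) and sits on a small rectified-noise floor; measured firing
  suppression is therefore a few percent smaller in magnitude than the
  generative suppression, more visibly for the (smaller) flexor effect.

## Intracellular module

[count_spikes()] counts upward threshold crossings (default −20 mV
absolute, 2-ms refractory; a `relative = TRUE` mode thresholds above the
trace median and is DC-offset invariant). [input_resistance()] is the
least-squares slope of steady-state voltage on injected current (200-ms
pulses, linear range), in MΩ. [coupling_amplitude()] implements the
collision protocol: the averaged orthodromic action potential (≥20 sweeps)
is subtracted from the averaged collided antidromic response after
10-ms-pre-stimulus baseline alignment; the peak of the difference in a
1–10 ms post-stimulus window (configurable — the exact window is a
convention) is the electrotonic coupling amplitude, and
[voltage_independent()] flags gap-junction-like profiles (<10% spread
across holding potentials).

## Numerical choices and degenerate inputs

* Angles wrap to (−180°, 180°]; ridge ties break toward the lowest
  frequency; parabolic refinement is clamped to ±half a grid step.
* Zero control means (dead trials) are errors — such trials should already
  have been discarded by the validity rule.
* All generation and resampling is seeded; the bootstrap draws its full
  index stream up-front so chunked evaluation is bit-reproducible.
* Problem sizes used by the packaged studies: unit tests synthesize at
  500 Hz with 2–5 experiments; the recovery study uses the full 25 vs 28
  experiments × 4 trials at 1 kHz; type-I calibration uses 100 series-level
  replicates at 1,000 iterations. These sizes are the package's choices,
  balancing statistical resolution against what a desk machine runs
  comfortably.

## Container format

One experiment per file: an RDS-serialized hierarchical list (`format =
"rootwave-container"`, version 1) holding per-trial sample matrices plus
channel/light metadata — bit-exact round-trip, schema-validated on read
with errors naming the missing field. A plain columnar CSV export (time
column + one column per channel, RFC-4180, with a JSON metadata sidecar)
provides interoperability. Proprietary acquisition formats (ABF etc.) are
out of scope.
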