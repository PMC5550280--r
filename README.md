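# rootwave

Quantification pipeline for **drug-induced locomotor-like rhythms recorded
from spinal ventral roots under optogenetic perturbation**, with a
ground-truth synthetic generator for calibration and end-to-end
parameter-recovery studies.

In the isolated neonatal rodent spinal cord, NMDA + serotonin evoke
rhythmic (~0.3–0.6 Hz) alternating bursting in the lumbar ventral roots —
fictive locomotion. Optogenetically hyperpolarizing motoneurons during a
60-s light epoch suppresses root firing by tens of percent, transiently
slows the rhythm by ~5–13%, shifts inter-root phasing by tens of degrees,
and is followed by post-light rebound. `rootwave` is for physiologists who
need to turn such multichannel neurograms into statistics: it implements
the full chain from raw trials to cohort-level pointwise bootstrap
comparisons.

## The analysis

For each 3-min trial (60 s pre-light / 60 s light / 60 s post-light),
aligned and trimmed to 170 s:

1. **Filtering.** Integrated neurogram per root: LP 200 Hz → HP 10 Hz →
   rectify → LP 5 Hz (all zero-phase Butterworth) — a proxy for pooled
   motoneuron firing. Slow drive potential: LP 200 Hz → band-pass
   0.01–5 Hz. Light step and pulse-train artifacts are removed first.
2. **Wavelet rhythm extraction.** Complex Morlet CWT (ω₀ = 6, 64
   log-spaced frequencies over 0.1–2 Hz, 3200 time points across the
   170 s). The instantaneous rhythm frequency is the in-band power ridge
   f(t) = argmax_f |W(f, t)|²; the inter-root phase is the cross-wavelet
   phase arg{W_A·W̄_B} along the joint ridge, wrapped to (−180°, 180°].
   10 s of wavelet edge effects are clipped at each end; trials whose
   ridge power collapses before or during the light are discarded, and
   experiments keep ≥3 valid trials or are excluded.
3. **Normalization.** Relative to the pre-light control window:
   100·(f/f̄_c − 1) for frequency, |Δφ| on the circle for phase,
   100·(y/ȳ_c − 1) for firing (integrated neurograms resampled at 19 Hz
   onto the common time base). Standard 10-s window means: control,
   start-light, end-light, after-light.
4. **Group statistics.** Per time point, a Welch t statistic between two
   cohorts of experiment-averaged series and a bootstrap p-value
   (shift-method null, experiments resampled with replacement, 10,000
   iterations): p = (1 + #{|t*| ≥ |t_obs|})/(n_iter + 1), displayed in
   tiers p<0.05 / 0.01 / 0.001 / 0.0001.

A synthetic generator (`synthetic_scenario()`, `generate_trial()`)
produces Poisson-burst multichannel trials with known frequency, phase,
and firing-modulation ground truth, so every stage can be validated by
parameter recovery. An intracellular module covers epoch spike counts,
I–V input resistance, and collision-protocol electrical-coupling
amplitudes.

## Worked example

```r
library(rootwave)

scArch <- synthetic_scenario(n_experiments = 8, trials_per_experiment = 4,
                             seed = 11)              # silencing cohort
scWT   <- wildtype_scenario(n_experiments = 8, trials_per_experiment = 4,
                            seed = 22)               # no light effects
res <- run_pipeline(scArch, scWT, pipeline_config(), seed = 5)

group_window_mean(res, "firing_pct.extensor", "start_light", "A")
group_window_mean(res, "freq_pct.bilateral_flexor", "start_light", "A")
render_comparison(res$comparisons$`firing_pct.extensor`, res$time_axis_s,
                  ylab = "change in MN firing (%)")
```

Running `analysis/04_aggregate_compare.R`, which executes exactly this
study, prints:

```
group A: 8 experiment(s) retained
group B: 8 experiment(s) retained
start_light: freq -5.7% | flexor firing -51.2% | extensor firing -78.0% | ipsi phase 34 deg
after_light: freq +7.2% | flexor firing +20.8% | extensor firing +19.6% | ipsi phase 1 deg
extensor-firing comparison: 12% of light-epoch points at p<0.001, 2% at p<0.0001
```

Reading: during the first 10 s of the light the silencing cohort's
extensor-root firing is ~78% below its pre-light baseline and the rhythm
runs ~5.7% slower; after the light both rebound above baseline. With only
8 experiments per cohort the experiment-resampling bootstrap-t null is
heavy-tailed, so few points reach the deepest display tier — at the full
study scale (25 vs 28 experiments, the size the acceptance study runs)
about 70% of the light epoch of the extensor-firing comparison sits at
p < 0.0001. (All numbers printed by the scripts themselves; cohorts are
synthetic, so they reflect the generator's effect scales.)

The numbered scripts under `analysis/` run the workflow in stages —
simulate (01), preprocess (02), wavelet rhythm extraction (03), aggregate
and compare (04), intracellular (05) — writing tables, figures and the
serialized pipeline configuration under `results/`.

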