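#!/usr/bin/env Rscript
# Intracellular analyses on simulated motoneuron sweeps: epoch spike
# counts under the light, I-V input resistance, and the collision-test
# electrical-coupling amplitude across holding potentials.

suppressMessages(library(rootwave))
set.seed(3)

## spike counts: a motoneuron firing at 4 Hz pre-light, suppressed to 1.7 Hz
fs <- 10000
spike <- c(seq(-48, 10, length.out = 10), seq(10, -48, length.out = 15))
v <- rep(-48, 180 * fs)
for (tt in c(sort(runif(230, 1, 59)), sort(runif(103, 61, 119)),
             sort(runif(251, 121, 179)))) {
  i <- round(tt * fs)
  v[i:(i + length(spike) - 1)] <- spike
}
counts <- count_spikes(icell_sweep(v, fs),
                       list(pre = c(0, 60), light = c(60, 120),
                            post = c(120, 180)))
cat(sprintf("spike counts pre/light/post: %d / %d / %d (light = %.1f%% of control)\n",
            counts[["pre"]], counts[["light"]], counts[["post"]],
            100 * counts[["light"]] / counts[["pre"]]))

## input resistance from a simulated 45-MOhm cell (200-ms pulses)
tt <- (0:(0.2 * fs - 1)) / fs
iv <- do.call(rbind, lapply(seq(-120, 120, by = 40), function(I_pA) {
  vi <- I_pA * 45 * 1e-3 * (1 - exp(-tt / 0.02)) + rnorm(length(tt), 0, 0.05)
  data.frame(injected_current_pA = I_pA,
             steady_voltage_mV = mean(vi[tt > 0.15]))
}))
cat(sprintf("input resistance: %.1f MOhm\n", input_resistance(iv)))

## collision protocol at three holding potentials
fs_c <- 20000
tc <- (0:(0.05 * fs_c - 1)) / fs_c
stim <- 0.01
ap <- 80 * exp(-((tc - stim - 0.002)^2) / (2 * 0.0005^2))
bump <- 1.2 * exp(-((tc - stim - 0.004)^2) / (2 * 0.001^2))
amps <- vapply(c(-70, -55, -45), function(hold) {
  ortho <- icell_sweep(hold + ap, fs_c, stim_times = stim)
  coll <- icell_sweep(hold + ap + bump, fs_c, stim_times = stim)
  coupling_amplitude(coll, ortho)$amplitude_mV
}, numeric(1))
cat(sprintf("coupling amplitudes at -70/-55/-45 mV: %.2f / %.2f / %.2f mV; voltage-independent: %s\n",
            amps[1], amps[2], amps[3], voltage_independent(amps)))
utils::write.csv(data.frame(holding_mV = c(-70, -55, -45),
                            coupling_mV = amps),
                 "results/icell_coupling.csv", row.names = FALSE)
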