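#!/usr/bin/env Rscript
# Preprocess one simulated trial: step-artifact correction, alignment
# trim, and the two filter chains (integrated neurogram + slow drive
# potential) for every root; writes a downsampled trace table.

suppressMessages(library(rootwave))

# trials were synthesized at 1 kHz; the acquisition-rate warning that
# read_trials raises for non-5/10-kHz data is expected here
trials <- suppressWarnings(read_trials("results/sim_arch_e01.rds"))
tr <- trials[[1]]
cat("Loaded", tr$experiment_id, "/", tr$trial_id, ":",
    nrow(tr$samples), "roots,", ncol(tr$samples) / tr$fs, "s at",
    tr$fs, "Hz\n")

for (i in seq_len(nrow(tr$samples))) {
  tr$samples[i, ] <- correct_step_artifact(tr$samples[i, ], tr$fs, tr$light)
}
tr <- align_trim(tr)
cat("Trimmed to", ncol(tr$samples) / tr$fs, "s; light at [",
    tr$light$onset_s, ",", tr$light$offset_s, ") s\n")

t19 <- seq(0, 170, by = 1 / 19)
tab <- data.frame(time_s = t19)
tnat <- (seq_len(ncol(tr$samples)) - 1) / tr$fs
for (i in seq_len(nrow(tr$samples))) {
  lab <- tr$channels[[i]]$label
  ig <- integrate_neurogram(tr$samples[i, ], tr$fs)
  sl <- extract_slow_potential(tr$samples[i, ], tr$fs)
  tab[[paste0(lab, "_integrated")]] <- stats::approx(tnat, ig$samples,
                                                     t19, rule = 2)$y
  tab[[paste0(lab, "_slow")]] <- stats::approx(tnat, sl$samples, t19,
                                               rule = 2)$y
}
utils::write.csv(tab, "results/preprocessed_e01_t1_19hz.csv",
                 row.names = FALSE)

supp <- 100 * (mean(tab$rL5_integrated[t19 >= 55 & t19 < 65]) /
                 mean(tab$rL5_integrated[t19 >= 10 & t19 < 55]) - 1)
cat(sprintf("rL5 integrated envelope, first 10 s of light vs control: %+.1f%%\n",
            supp))
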