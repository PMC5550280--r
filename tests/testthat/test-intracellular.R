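# Synthetic sweeps: a rhythmic membrane potential with stereotyped spikes.
mk_spiking_sweep <- function(n_pre, n_light, fs = 10000, v_rest = -48) {
  spike <- c(seq(v_rest, 10, length.out = 10), seq(10, v_rest, length.out = 15))
  v <- rep(v_rest, 180 * fs)
  place <- function(times) {
    for (tt in times) {
      i <- round(tt * fs)
      v[i:(i + length(spike) - 1)] <<- spike
    }
  }
  set.seed(n_pre + n_light)
  place(sort(stats::runif(n_pre, 1, 59)))
  place(sort(stats::runif(n_light, 61, 119)))
  icell_sweep(v, fs)
}

test_that("spike counts per epoch match constructed trains", {
  sw <- mk_spiking_sweep(100, 40)
  epochs <- list(pre = c(0, 60), light = c(60, 120), post = c(120, 180))
  counts <- count_spikes(sw, epochs)
  expect_identical(unname(counts[c("pre", "light")]), c(100, 40))
  # percent-of-control firing during the light
  expect_equal(100 * counts[["light"]] / counts[["pre"]], 40)
  flat <- icell_sweep(rep(-48, 10000), 10000)
  expect_identical(unname(count_spikes(flat, list(a = c(0, 0.5), b = c(0.5, 1)))),
                   c(0, 0))
  expect_error(count_spikes(flat, list(a = c(0, 10))), "outside the sweep")
})

test_that("relative-threshold spike counting is DC-offset invariant", {
  sw <- mk_spiking_sweep(80, 30)
  epochs <- list(pre = c(0, 60), light = c(60, 120))
  base <- count_spikes(sw, epochs, threshold_mV = 25, relative = TRUE)
  for (dc in c(-30, 15, 40)) {
    shifted <- icell_sweep(sw$voltage + dc, sw$fs)
    expect_identical(count_spikes(shifted, epochs, threshold_mV = 25,
                                  relative = TRUE), base)
  }
})

test_that("the refractory period suppresses double counting", {
  fs <- 10000
  v <- rep(-50, fs)
  # a noisy spike crest that crosses threshold twice within 1 ms
  v[1000:1010] <- c(-10, 5, -22, 6, 8, 0, -10, -25, -30, -40, -50)
  counts <- count_spikes(icell_sweep(v, fs), list(all = c(0, 0.1)))
  expect_identical(unname(counts), 1)
})

test_that("I-V slope recovers input resistance", {
  iv <- data.frame(injected_current_pA = c(-100, 0, 100),
                   steady_voltage_mV = c(-5, 0, 5))
  expect_equal(input_resistance(iv), 50)
  expect_error(input_resistance(iv[1, ]), "at least 3")
  # simulated RC cell, R = 45 MOhm, tau = 20 ms, 200-ms pulses
  fs <- 10000; R_MOhm <- 45; tau <- 0.02
  t <- (0:(0.2 * fs - 1)) / fs
  set.seed(90)
  iv2 <- do.call(rbind, lapply(seq(-120, 120, by = 40), function(I_pA) {
    v <- I_pA * R_MOhm * 1e-3 * (1 - exp(-t / tau)) + rnorm(length(t), 0, 0.05)
    data.frame(injected_current_pA = I_pA,
               steady_voltage_mV = mean(v[t > 0.15]))  # steady window
  }))
  expect_equal(input_resistance(iv2), 45, tolerance = 1 / 45)
})

test_that("collision subtraction isolates an injected coupling potential", {
  fs <- 20000
  t <- (0:(0.05 * fs - 1)) / fs
  stim <- 0.01
  ap <- 80 * exp(-((t - stim - 0.002)^2) / (2 * 0.0005^2))  # orthodromic AP
  bump <- 1.2 * exp(-((t - stim - 0.004)^2) / (2 * 0.001^2))  # coupling
  ortho <- icell_sweep(-55 + ap, fs, stim_times = stim)
  coll <- icell_sweep(-55 + ap + bump, fs, stim_times = stim)
  res <- coupling_amplitude(coll, ortho)
  expect_equal(res$amplitude_mV, 1.2, tolerance = 0.05 / 1.2)
  # identical inputs -> exactly zero
  res0 <- coupling_amplitude(ortho, ortho)
  expect_identical(res0$amplitude_mV, 0)
  # linear in the injected bump amplitude
  coll2 <- icell_sweep(-55 + ap + 2.5 * bump, fs, stim_times = stim)
  res2 <- coupling_amplitude(coll2, ortho)
  expect_equal(res2$amplitude_mV / res$amplitude_mV, 2.5, tolerance = 0.01)
  # baseline (holding-potential) differences are removed by alignment
  coll3 <- icell_sweep(-70 + ap + bump, fs, stim_times = stim)
  res3 <- coupling_amplitude(coll3, ortho)
  expect_equal(res3$amplitude_mV, 1.2, tolerance = 0.05 / 1.2)
  expect_warning(coupling_amplitude(coll, ortho, n_sweeps = 5),
                 "fewer than 20")
})

test_that("voltage independence flags gap-junction-like amplitude profiles", {
  expect_true(voltage_independent(c(1.20, 1.15, 1.22)))
  expect_false(voltage_independent(c(1.2, 0.6, 0.2)))
})

test_that("sweep CSV import reconstructs rate and voltage", {
  f <- withr::local_tempfile(fileext = ".csv")
  fs <- 10000
  df <- data.frame(time_s = (0:999) / fs, voltage_mV = rnorm(1000, -50),
                   current_pA = rep(0, 1000))
  utils::write.csv(df, f, row.names = FALSE)
  sw <- read_sweep_csv(f, stim_times = 0.05)
  expect_equal(sw$fs, fs, tolerance = 1e-6)
  expect_equal(sw$voltage, df$voltage_mV)
})
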